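#' Remove refractory-period violations from a spike train
#'
#' Sequential scan: a spike is kept only if it falls at least `refractory`
#' seconds after the last kept spike, so every output inter-spike interval is
#' at least the refractory period. The scan is idempotent, order-preserving,
#' and never removes the first spike.
#'
#' @param spike_times sorted numeric vector of spike times (seconds).
#' @param refractory refractory period, seconds (default 2.5 ms).
#' @return `list(times, n_removed)`.
#' @examples
#' clean_refractory(c(0, 0.001, 0.002, 0.0024, 0.010))
#' @export
clean_refractory <- function(spike_times, refractory = 0.0025) {
  if (!is.numeric(spike_times)) stopf("spike_times must be numeric")
  if (is.unsorted(spike_times)) stopf("spike_times must be sorted non-decreasing")
  if (!length(spike_times)) return(list(times = numeric(0), n_removed = 0L))
  keep <- refractory_keep_grouped(as.numeric(spike_times),
                                  rep(1L, length(spike_times)), refractory)
  list(times = spike_times[keep], n_removed = sum(!keep))
}

#' Refractory-clean every unit of a recording
#'
#' @param recording an `mea_recording`.
#' @param refractory refractory period, seconds.
#' @return The cleaned recording, with per-unit removal counts in
#'   `attr(, "refractory_removed")`.
#' @export
clean_recording <- function(recording, refractory = 0.0025) {
  stopifnot(inherits(recording, "mea_recording"))
  removed <- integer(length(recording$spikes))
  names(removed) <- names(recording$spikes)
  for (uid in names(recording$spikes)) {
    cl <- clean_refractory(recording$spikes[[uid]], refractory)
    recording$spikes[[uid]] <- cl$times
    removed[uid] <- cl$n_removed
  }
  attr(recording, "refractory_removed") <- removed
  recording
}

# PCA of a waveform matrix with noise-floor component retention: keep
# principal components whose eigenvalue exceeds `noise_mult` times the median
# eigenvalue (the median tracks the flat noise floor), capped at `max_pc`.
# Returns the eigen-scaled scores (`scores`, used for clustering) and the
# per-component SD-normalized scores (`znorm`): distances for the 1.4 outlier
# cut are measured in `znorm`, so the between-cluster spread is part of the
# scale and members of well-separated clusters sit well inside the threshold.
waveform_pc_space <- function(waveforms, max_pc = 3L, noise_mult = 2) {
  pc <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  # noise-floor rule with a relative floor so numerically-zero components of
  # noiseless data are never retained
  k <- sum(ev > pmax(noise_mult * stats::median(ev), 1e-9 * ev[1]))
  k <- max(1L, min(k, max_pc, ncol(pc$x)))
  z <- pc$x[, seq_len(k), drop = FALSE]
  list(scores = z,
       znorm = scale(z, center = FALSE, scale = apply(z, 2, stats::sd)))
}

# Monte-Carlo calibrated multivariate test of cluster distinctness. A naive
# MANOVA on k-means labels is anti-conservative: any k-means split of a single
# Gaussian separates the means, and the PCA step selects the directions along
# which the sample happens to spread most. The observed Pillai trace is
# therefore compared with Pillai traces obtained by the *identical*
# PCA + k-means pipeline applied to multivariate-normal null waveforms with
# the covariance of the observed waveforms (the single-cluster hypothesis).
calibrated_manova_p <- function(waveforms, k, reps = 199L, seed = 1L,
                                subsample = 300L) {
  n <- nrow(waveforms)
  if (k < 2 || n < 2 * k) return(NA_real_)
  sub <- if (n > subsample) {
    with_seed(derive_seed(seed, 881L), sample.int(n, subsample))
  } else seq_len(n)
  # Pillai trace tr(H (H+E)^-1) computed directly (H+E = total SSCP); reduces
  # to the between/total sum-of-squares ratio (eta^2) in one dimension.
  pillai <- function(zz, cl) {
    if (length(unique(cl)) < 2) return(0)
    zz <- as.matrix(zz)
    mu <- colMeans(zz)
    zc <- sweep(zz, 2, mu)
    tot <- crossprod(zc)
    B <- matrix(0, ncol(zz), ncol(zz))
    for (g in unique(cl)) {
      sel <- cl == g
      d <- colMeans(zz[sel, , drop = FALSE]) - mu
      B <- B + sum(sel) * tcrossprod(d)
    }
    inv <- try(solve(tot), silent = TRUE)
    if (inherits(inv, "try-error")) return(0)
    sum(diag(B %*% inv))
  }
  split_stat <- function(wf) {
    z <- tryCatch(waveform_pc_space(wf)$scores, error = function(e) NULL)
    if (is.null(z)) return(NA_real_)
    km <- tryCatch(stats::kmeans(z, k, nstart = 3, iter.max = 25),
                   error = function(e) NULL)
    if (is.null(km)) return(NA_real_)
    pillai(z, km$cluster)
  }
  ws <- waveforms[sub, , drop = FALSE]
  m <- length(sub)
  mu <- colMeans(ws)
  sig <- stats::cov(ws)
  ridge <- 1e-8 * mean(diag(sig)) + 1e-300
  ch <- try(chol(sig + diag(ridge, ncol(ws))), silent = TRUE)
  if (inherits(ch, "try-error")) return(NA_real_)
  with_seed(derive_seed(seed, 882L), {
    obs <- split_stat(ws)
    if (!is.finite(obs)) return(NA_real_)
    null_stat <- vapply(seq_len(reps), function(r) {
      wf0 <- sweep(matrix(stats::rnorm(m * ncol(ws)), m) %*% ch, 2, mu, `+`)
      s <- split_stat(wf0)
      if (is.finite(s)) s else 1
    }, numeric(1))
    (1 + sum(null_stat >= obs)) / (reps + 1)
  })
}

#' Sort spike waveforms into units
#'
#' Reproduces the offline sorting stage for one electrode: PCA of the waveform
#' snippets (components retained by a noise-floor rule, at most 3), K-means
#' into `expected_units` clusters, and removal of spikes whose distance to
#' their cluster centroid in the SD-standardized PC space exceeds
#' `mahal_threshold` (1.4 by default, the stricter end of the 1.8-1.4 range).
#' Cluster distinctness is assessed with a Monte-Carlo calibrated MANOVA
#' (Pillai trace against k-means splits of matched multivariate-normal null
#' data): sorted units are accepted when that p-value is below 0.01. If the
#' distance cut would remove more than `max_removal` of the spikes, the result
#' is flagged for manual review instead of silently over-deleting.
#'
#' @param waveforms numeric matrix, one spike per row (equal snippet lengths).
#' @param expected_units number of units expected on the electrode (>= 1).
#' @param mahal_threshold outlier distance threshold, conventionally in
#'   `[1.4, 1.8]`.
#' @param max_removal maximal tolerated removal fraction (default 0.1).
#' @param seed seed for the K-means multi-start and MANOVA calibration.
#' @param manova_reps Monte-Carlo replicates for the calibrated MANOVA
#'   (199 resolves p-values down to 0.005).
#' @return `list(cluster, removed, distance, manova_p, n_pc, flag_excess_removal,
#'   valid)`; `removed` is the logical removal mask, `valid` is `FALSE` when
#'   the clusters are not statistically distinct or removal was excessive.
#' @export
sort_waveforms <- function(waveforms, expected_units, mahal_threshold = 1.4,
                           max_removal = 0.1, seed = 1L, manova_reps = 199L) {
  waveforms <- as.matrix(waveforms)
  if (!is_scalar_num(expected_units) || expected_units < 1)
    stopf("expected_units must be >= 1")
  expected_units <- as.integer(expected_units)
  if (nrow(waveforms) < 2L * expected_units)
    stopf("need at least 2 spikes per candidate unit")
  if (mahal_threshold <= 0) stopf("mahal_threshold must be positive")
  if (all(apply(waveforms, 2, stats::sd) < 1e-12))
    stopf("degenerate input: all waveforms identical; refusing to cluster")
  ps <- waveform_pc_space(waveforms)
  if (expected_units == 1L) {
    cluster <- rep(1L, nrow(ps$scores))
  } else {
    cluster <- kmeans_multistart(ps$scores, expected_units, seed = seed)$cluster
  }
  z <- ps$znorm
  centroids <- do.call(rbind, lapply(seq_len(expected_units), function(g)
    colMeans(z[cluster == g, , drop = FALSE])))
  d <- sqrt(rowSums((z - centroids[cluster, , drop = FALSE])^2))
  removed <- d > mahal_threshold
  frac <- mean(removed)
  flag_excess <- frac > max_removal
  keep <- !removed
  p <- calibrated_manova_p(waveforms[keep, , drop = FALSE], expected_units,
                           reps = manova_reps, seed = seed)
  valid <- !flag_excess && (expected_units == 1L || (is.finite(p) && p < 0.01))
  if (flag_excess)
    warnf("distance cut would remove %.1f%% of spikes (> %.0f%%); flagged for manual review",
          100 * frac, 100 * max_removal)
  list(cluster = cluster, removed = removed, distance = d, manova_p = p,
       n_pc = ncol(z), flag_excess_removal = flag_excess, valid = valid)
}

#' Run waveform sorting over all electrodes of a recording
#'
#' Applies [sort_waveforms()] electrode by electrode (expected unit count =
#' units recorded on the electrode) and drops the spikes removed by the
#' distance cut from the recording. Electrodes whose proposed removal exceeds
#' `max_removal` are left untouched and flagged.
#'
#' @param recording an `mea_recording`.
#' @param bank an [generate_waveforms()] bank for the recording.
#' @param mahal_threshold,max_removal,seed,manova_reps passed to
#'   [sort_waveforms()].
#' @return `list(recording, report, fraction_removed, removed_by_unit)`;
#'   `report` has one row per electrode, `removed_by_unit` maps each unit to
#'   the logical removal mask over its original spikes.
#' @export
sort_recording <- function(recording, bank, mahal_threshold = 1.4,
                           max_removal = 0.1, seed = 1L, manova_reps = 199L) {
  stopifnot(inherits(recording, "mea_recording"), inherits(bank, "mea_waveforms"))
  units <- recording$units
  removed_by_unit <- lapply(recording$spikes, function(t) rep(FALSE, length(t)))
  rows <- list()
  for (el in sort(unique(units$electrode_id))) {
    uids <- units$unit_id[units$electrode_id == el]
    uids <- uids[vapply(uids, function(u) length(bank[[u]]$spike_times) > 0, logical(1))]
    if (!length(uids)) next
    wf <- do.call(rbind, lapply(uids, function(u) bank[[u]]$waveforms))
    src_unit <- rep(uids, vapply(uids, function(u) nrow(bank[[u]]$waveforms), integer(1)))
    src_idx <- unlist(lapply(uids, function(u) seq_len(nrow(bank[[u]]$waveforms))))
    if (nrow(wf) < 2L * length(uids)) next
    res <- sort_waveforms(wf, expected_units = length(uids),
                          mahal_threshold = mahal_threshold,
                          max_removal = max_removal,
                          seed = derive_seed(seed, 9000L + el),
                          manova_reps = manova_reps)
    rm_mask <- res$removed & !res$flag_excess_removal
    for (j in which(rm_mask)) {
      removed_by_unit[[src_unit[j]]][src_idx[j]] <- TRUE
    }
    rows[[length(rows) + 1L]] <-
      data.frame(electrode_id = el, n_units = length(uids), n_spikes = nrow(wf),
                 n_removed = sum(rm_mask), manova_p = res$manova_p,
                 n_pc = res$n_pc, flagged = res$flag_excess_removal,
                 valid = res$valid)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(electrode_id = integer(0), n_units = integer(0),
               n_spikes = integer(0), n_removed = integer(0),
               manova_p = numeric(0), n_pc = integer(0),
               flagged = logical(0), valid = logical(0))
  out <- recording
  for (uid in names(out$spikes)) {
    out$spikes[[uid]] <- out$spikes[[uid]][!removed_by_unit[[uid]]]
  }
  total <- sum(lengths(recording$spikes))
  list(recording = out, report = report,
       fraction_removed = if (total > 0) sum(report$n_removed) / total else 0,
       removed_by_unit = removed_by_unit)
}

#' Exclude irregularly responding electrodes
#'
#' Drops electrodes whose aggregate firing is unreliable: mean rate below
#' `min_rate` or silence in more than `max_silent_fraction` of
#' `segment_len`-second segments. Exclusions are recorded in
#' `attr(, "excluded_electrodes")`.
#'
#' @param recording an `mea_recording`.
#' @param min_rate minimal electrode-aggregate rate, Hz.
#' @param max_silent_fraction maximal tolerated fraction of silent segments.
#' @param segment_len segment length for the silence criterion, seconds.
#' @return The restricted recording; errors if nothing survives.
#' @export
exclude_irregular_electrodes <- function(recording, min_rate = 0.05,
                                         max_silent_fraction = 0.5,
                                         segment_len = 600) {
  stopifnot(inherits(recording, "mea_recording"))
  units <- recording$units
  dur <- recording$duration
  n_seg <- max(1L, floor(dur / segment_len))
  seg_edges <- seq(0, by = segment_len, length.out = n_seg + 1L)
  seg_edges[n_seg + 1L] <- dur
  drop <- logical(0); keep_el <- integer(0)
  excluded <- list()
  for (el in sort(unique(units$electrode_id))) {
    uids <- units$unit_id[units$electrode_id == el]
    tms <- sort(unlist(recording$spikes[uids], use.names = FALSE))
    rate <- length(tms) / dur
    seg_counts <- if (length(tms)) {
      tabulate(findInterval(tms, seg_edges, rightmost.closed = TRUE), n_seg)
    } else rep(0L, n_seg)
    silent_frac <- mean(seg_counts == 0)
    if (rate < min_rate || silent_frac > max_silent_fraction) {
      excluded[[as.character(el)]] <- list(rate = rate, silent_fraction = silent_frac)
    } else {
      keep_el <- c(keep_el, el)
    }
  }
  if (!length(keep_el)) stopf("all electrodes excluded as irregular")
  keep_units <- units$electrode_id %in% keep_el
  out <- recording
  out$units <- units[keep_units, , drop = FALSE]
  rownames(out$units) <- NULL
  out$spikes <- recording$spikes[out$units$unit_id]
  attr(out, "excluded_electrodes") <- excluded
  out
}
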