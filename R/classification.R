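# Standardize a feature matrix and run PCA keeping components up to >= 90%
# cumulative variance. Returns the eigen-scaled scores (`scores`, used for
# clustering: inter-cluster structure keeps its weight) and the per-component
# SD-normalized scores (`znorm`, the distance convention of the 1.4 outlier
# cut, shared with the waveform sorter).
pca_space <- function(x, var_target = 0.9) {
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 1e-12
  if (!any(keep)) stopf("degenerate features: no variance across observations")
  xs <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- max(1L, which(cum >= var_target - 1e-12)[1])
  z <- pc$x[, seq_len(k), drop = FALSE]
  list(scores = z,
       znorm = scale(z, center = FALSE, scale = apply(z, 2, stats::sd)))
}

bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / s^3
  g2 <- mean((x - m)^4) / s^4 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Classify units into excitatory and inhibitory clusters
#'
#' Unsupervised separation of the two neuronal populations from their firing
#' statistics (spike width is deliberately not used). Features — Fano factor,
#' mean burst duration, mean spike number and intra-burst spike rate, which are
#' bimodal across units in these cultures — are standardized and reduced by PCA
#' (components up to 90% variance), clustered by seeded multi-start K-means
#' with K = 2, and units farther than `mahal_threshold` (default 1.4) from
#' their cluster centroid in the SD-standardized PC space are set aside as
#' outliers. The larger cluster is labelled excitatory, matching the
#' neocortical excitatory/inhibitory proportions.
#'
#' @param stats a [segment_stats()] data frame (or any data frame with the
#'   feature columns and `unit_id`).
#' @param features feature columns to use.
#' @param mahal_threshold outlier distance threshold.
#' @param seed K-means multi-start seed.
#' @return An object of class `unit_classes`: `labels` (named vector with
#'   levels `excitatory`, `inhibitory`, `outlier`), `centroids`, `ff_bimodality`
#'   (bimodality coefficient of the Fano factor, informational), `n_pc`.
#' @export
classify_units <- function(stats, features = c("ff", "bd_mean", "sn_mean", "ibsr"),
                           mahal_threshold = 1.4, seed = 1L) {
  if (!all(c("unit_id", features) %in% names(stats)))
    stopf("stats must contain unit_id and feature columns %s",
          paste(features, collapse = ", "))
  x <- as.matrix(stats[, features, drop = FALSE])
  ok <- stats::complete.cases(x)
  ids <- stats$unit_id[ok]
  x <- x[ok, , drop = FALSE]
  if (nrow(x) < 10) stopf("need at least 10 units with complete statistics")
  if (nrow(unique(x)) < 2) stopf("degenerate: all units have identical features")
  ps <- pca_space(x)
  km <- kmeans_multistart(ps$scores, 2L, seed = seed)
  cl <- km$cluster
  z <- ps$znorm
  centroids <- do.call(rbind, lapply(1:2, function(g)
    colMeans(z[cl == g, , drop = FALSE])))
  d <- sqrt(rowSums((z - centroids[cl, , drop = FALSE])^2))
  outlier <- d > mahal_threshold
  sizes <- vapply(1:2, function(g) sum(cl == g & !outlier), integer(1))
  exc_cluster <- which.max(sizes) # larger cluster = excitatory
  labels <- ifelse(outlier, "outlier",
                   ifelse(cl == exc_cluster, "excitatory", "inhibitory"))
  names(labels) <- ids
  structure(list(labels = labels, centroids = centroids,
                 ff_bimodality = bimodality_coefficient(stats$ff[ok]),
                 n_pc = ncol(z), distance = stats::setNames(d, ids)),
            class = "unit_classes")
}

# Per-up-state feature matrix for network-state sorting: the pooled SN time
# histogram summarized by its first `n_hist_bins` bins, the total pooled spike
# count, the number of engaged neurons, and the burst duration.
upstate_features <- function(recording, upstates, bin = 0.1, n_hist_bins = 10L) {
  B <- nrow(upstates)
  hist <- matrix(0, B, n_hist_bins)
  pooled <- sort(unlist(recording$spikes, use.names = FALSE))
  for (b in seq_len(B)) {
    lo <- findInterval(upstates$start[b] - 1e-12, pooled)
    hi <- findInterval(upstates$end[b] + 1e-12, pooled)
    if (hi <= lo) next
    off <- pooled[(lo + 1L):hi] - upstates$start[b]
    idx <- floor(off / bin) + 1L
    idx <- idx[idx <= n_hist_bins]
    hist[b, ] <- tabulate(idx, n_hist_bins)
  }
  cbind(hist, sn = upstates$pooled_sn, n_engaged = upstates$n_engaged,
        bd = upstates$bd)
}

#' Sort up-states into four network states
#'
#' PCA-based state classification of the detected up-states from their pooled
#' spike-number time histogram, number of engaged neurons, and burst duration.
#' Features are standardized, reduced to components explaining at least 90% of
#' the variance, and clustered by seeded multi-start K-means with K = 4; the
#' states are relabelled 1-4 by ascending mean pooled spike number, so state 1
#' holds the weakest (shortest) bursts and state 4 the strongest.
#'
#' @param recording an `mea_recording`.
#' @param upstates detected up-states (at least 40).
#' @param bin time-histogram bin, seconds.
#' @param n_hist_bins histogram bins retained as features.
#' @param k number of states (4 in this analysis tradition).
#' @param seed K-means multi-start seed.
#' @return An object of class `state_assignment`: `state` (integer vector per
#'   up-state), `centroids`, `mean_sn` (per state), `features` (definition
#'   record).
#' @export
classify_states <- function(recording, upstates, bin = 0.1, n_hist_bins = 10L,
                            k = 4L, seed = 1L) {
  if (nrow(upstates) < 40) stopf("need at least 40 up-states to sort states")
  x <- upstate_features(recording, upstates, bin = bin, n_hist_bins = n_hist_bins)
  if (nrow(unique(x)) < k) stopf("fewer than %d distinct up-state feature vectors", k)
  z <- pca_space(x)$scores
  km <- kmeans_multistart(z, k, seed = seed)
  raw <- km$cluster
  mean_sn <- vapply(seq_len(k), function(g) mean(upstates$pooled_sn[raw == g]),
                    numeric(1))
  relabel <- match(seq_len(k), order(mean_sn)) # ascending mean SN -> 1..k
  state <- relabel[raw]
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(z[state == g, , drop = FALSE])))
  structure(list(state = state,
                 centroids = centroids,
                 mean_sn = sort(mean_sn),
                 features = list(bin = bin, n_hist_bins = n_hist_bins,
                                 extras = c("pooled_sn", "n_engaged", "bd"))),
            class = "state_assignment")
}

#' Fraction of a unit class engaged in a network state
#'
#' Mean, over the up-states of one state, of the fraction of the class's units
#' that fire at least one spike inside the up-state. In control cultures about
#' 60% of excitatory units engage in state-1 up-states and almost all in state
#' 4, while inhibitory units are always engaged.
#'
#' @param recording an `mea_recording`.
#' @param upstates detected up-states.
#' @param states a [classify_states()] assignment (or integer vector).
#' @param unit_classes a [classify_units()] assignment (or named label vector).
#' @param class `"excitatory"` or `"inhibitory"`.
#' @param state state index (1-4).
#' @return The engagement probability.
#' @export
engagement_fraction <- function(recording, upstates, states, unit_classes,
                                class = c("excitatory", "inhibitory"),
                                state = 1L) {
  class <- match.arg(class)
  st <- if (inherits(states, "state_assignment")) states$state else states
  labels <- if (inherits(unit_classes, "unit_classes")) unit_classes$labels else unit_classes
  sel <- which(st == state)
  if (!length(sel)) stopf("state %d contains no up-states", state)
  members <- names(labels)[labels == class]
  if (!length(members)) stopf("no units labelled %s", class)
  cnt <- unit_burst_counts(recording, upstates[sel, , drop = FALSE])
  engaged <- cnt[members, , drop = FALSE] >= 1L
  mean(colMeans(engaged))
}

#' @export
print.unit_classes <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("excitatory", "inhibitory", "outlier")))
  cat(sprintf("<unit_classes> %d excitatory, %d inhibitory, %d outlier (FF bimodality %.2f)\n",
              tab["excitatory"], tab["inhibitory"], tab["outlier"],
              x$ff_bimodality))
  invisible(x)
}

#' @export
print.state_assignment <- function(x, ...) {
  cat("<state_assignment>", length(x$state), "up-states in",
      length(x$mean_sn), "states; mean pooled SN:",
      paste(sprintf("%.1f", x$mean_sn), collapse = ", "), "\n")
  invisible(x)
}
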