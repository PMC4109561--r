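empty_upstates <- function(duration = 0) {
  out <- data.frame(start = numeric(0), end = numeric(0), bd = numeric(0),
                    n_engaged = integer(0), pooled_sn = integer(0))
  attr(out, "duration") <- duration
  class(out) <- c("upstates", "data.frame")
  out
}

# Per-unit spike counts inside each up-state interval: units x up-states matrix.
unit_burst_counts <- function(recording, upstates) {
  n <- length(recording$spikes)
  B <- nrow(upstates)
  cnt <- matrix(0L, n, B, dimnames = list(names(recording$spikes), NULL))
  if (B == 0) return(cnt)
  for (i in seq_len(n)) {
    su <- recording$spikes[[i]]
    if (!length(su)) next
    cnt[i, ] <- findInterval(upstates$end + 1e-12, su) -
      findInterval(upstates$start - 1e-12, su)
  }
  cnt
}

#' Detect network up-states with a sliding-window hysteresis procedure
#'
#' A running window (default 10 ms, stepped every `step` seconds) counts the
#' pooled all-unit spikes. An up-state opens at the first window whose count
#' reaches `high_thr` and closes when the count stays below `low_thr` for at
#' least `min_interburst` seconds, so consecutive up-states are always
#' separated by at least `min_interburst` of quiet; the two thresholds form the
#' hysteresis that captures both short and very long (seizure-like) bursts
#' without fragmenting them. Up-state boundaries are snapped to the first and
#' last pooled spike inside the interval.
#'
#' @param recording an `mea_recording` (cleaned).
#' @param window running-window length, seconds (conventional range
#'   0.005-0.1).
#' @param high_thr opening threshold, spikes per window. Default: a quarter of
#'   the unit count (at least `low_thr`).
#' @param low_thr closing threshold, spikes per window.
#' @param min_interburst minimum quiet period that closes an up-state, seconds.
#' @param step window step, seconds.
#' @return An `upstates` data frame: `start`, `end`, `bd`, `n_engaged`
#'   (units with >= 1 spike inside), `pooled_sn` (pooled spike count), with the
#'   recording duration and detector settings in attributes.
#' @export
detect_upstates <- function(recording, window = 0.01, high_thr = NULL,
                            low_thr = 2, min_interburst = 0.1, step = 0.001) {
  stopifnot(inherits(recording, "mea_recording"))
  duration <- recording$duration
  pooled <- sort(unlist(recording$spikes, use.names = FALSE))
  if (!length(pooled)) return(empty_upstates(duration))
  n_units <- length(recording$spikes)
  if (is.null(high_thr)) high_thr <- max(0.25 * n_units, low_thr)
  if (low_thr <= 0 || high_thr <= 0) stopf("thresholds must be positive")
  if (low_thr > high_thr) stopf("low_thr must not exceed high_thr")
  if (window <= 0 || step <= 0 || min_interburst <= 0)
    stopf("window, step and min_interburst must be positive")

  w_starts <- seq(0, max(duration - window, 0), by = step)
  cnt <- findInterval(w_starts + window, pooled) - findInterval(w_starts, pooled)

  lowrun <- cnt < low_thr
  r <- rle(lowrun)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  L <- ceiling(min_interburst / step)
  sep <- which(r$values & r$lengths >= L)

  # candidate segments = index ranges between the long low runs
  seg_lo <- c(1L, run_end[sep] + 1L)
  seg_hi <- c(run_start[sep] - 1L, length(cnt))
  keep_seg <- seg_lo <= seg_hi
  seg_lo <- seg_lo[keep_seg]; seg_hi <- seg_hi[keep_seg]

  starts <- numeric(0); ends <- numeric(0)
  for (s in seq_along(seg_lo)) {
    i1 <- seg_lo[s]; i2 <- seg_hi[s]
    hi_rel <- which(cnt[i1:i2] >= high_thr)
    if (!length(hi_rel)) next
    t_open <- w_starts[i1 - 1L + hi_rel[1L]]
    t_close <- w_starts[i2] + window
    first_idx <- findInterval(t_open, pooled) + 1L
    last_idx <- findInterval(t_close + 1e-12, pooled)
    if (last_idx <= first_idx) next # need a positive-duration spike span
    starts <- c(starts, pooled[first_idx])
    ends <- c(ends, pooled[last_idx])
  }
  out <- data.frame(start = starts, end = ends, bd = ends - starts)
  out <- out[out$bd > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("upstates", "data.frame")
  attr(out, "duration") <- duration
  attr(out, "params") <- list(window = window, high_thr = high_thr,
                              low_thr = low_thr, min_interburst = min_interburst,
                              step = step)
  cntm <- unit_burst_counts(recording, out)
  out$n_engaged <- as.integer(colSums(cntm >= 1L))
  out$pooled_sn <- as.integer(colSums(cntm))
  out
}

#' Annotate per-unit bursts within detected up-states
#'
#' For every engaged unit of every up-state, collects the unit's spikes inside
#' the interval into one burst annotation, with the conventional rules for
#' sparse participation: a single spike is assigned a burst duration of 2 ms
#' and a spike number of 1; exactly two spikes give BD = their inter-spike
#' interval and SN = 2; three or more spikes give BD = last - first spike time.
#' Units without spikes in the interval do not appear.
#'
#' @param upstates an `upstates` data frame from [detect_upstates()].
#' @param recording the `mea_recording` the up-states were detected on.
#' @return A long data frame with columns `upstate`, `unit_id`, `sn`,
#'   `bd_unit` (seconds), `t_first`, `t_last`.
#' @export
annotate_unit_bursts <- function(upstates, recording) {
  stopifnot(inherits(recording, "mea_recording"))
  B <- nrow(upstates)
  res <- vector("list", length(recording$spikes))
  for (i in seq_along(recording$spikes)) {
    uid <- names(recording$spikes)[i]
    su <- recording$spikes[[i]]
    if (!length(su) || B == 0) next
    lo <- findInterval(upstates$start - 1e-12, su)
    hi <- findInterval(upstates$end + 1e-12, su)
    nb <- hi - lo
    bs <- which(nb >= 1L)
    if (!length(bs)) next
    sn <- nb[bs]
    t_first <- su[lo[bs] + 1L]
    t_last <- su[hi[bs]]
    bd_unit <- ifelse(sn == 1L, 0.002, t_last - t_first)
    res[[i]] <- data.frame(upstate = bs, unit_id = uid, sn = sn,
                           bd_unit = bd_unit, t_first = t_first,
                           t_last = t_last, stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(upstate = integer(0), unit_id = character(0),
                      sn = integer(0), bd_unit = numeric(0),
                      t_first = numeric(0), t_last = numeric(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$upstate, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard tonically firing units
#'
#' Units that keep firing through the down-states (typically one or two per
#' network) distort the population burst statistics; this removes every unit
#' whose firing rate outside the detected up-states exceeds
#' `down_state_rate_max`.
#'
#' @param recording an `mea_recording`.
#' @param upstates detected up-states on this recording.
#' @param down_state_rate_max maximal tolerated down-state rate, Hz.
#' @return The recording without tonic units; removed ids in
#'   `attr(, "tonic_removed")`.
#' @export
discard_tonic_units <- function(recording, upstates, down_state_rate_max = 0.1) {
  stopifnot(inherits(recording, "mea_recording"))
  dur <- recording$duration
  up_time <- sum(upstates$bd)
  down_time <- max(dur - up_time, 1e-9)
  cntm <- unit_burst_counts(recording, upstates)
  in_burst <- if (nrow(upstates)) rowSums(cntm) else rep(0, length(recording$spikes))
  total <- lengths(recording$spikes)
  down_rate <- (total - in_burst) / down_time
  tonic <- names(recording$spikes)[down_rate > down_state_rate_max]
  out <- recording
  if (length(tonic)) {
    keep <- !(out$units$unit_id %in% tonic)
    out$units <- out$units[keep, , drop = FALSE]
    rownames(out$units) <- NULL
    out$spikes <- out$spikes[out$units$unit_id]
  }
  attr(out, "tonic_removed") <- tonic
  out
}

#' Auto-tune the up-state detector for a recording
#'
#' Grid search over window length, opening/closing thresholds and minimum
#' interburst length. The objective is the temporal Jaccard agreement between
#' the detected up-state coverage and a smoothed population-rate reference mask
#' (50 ms bins, boxcar-smoothed over 0.25 s, active where the smoothed count
#' exceeds 5% of its 99th percentile). Deterministic: ties resolve to the
#' first grid point.
#'
#' @param recording an `mea_recording` of at least 10 minutes.
#' @param windows,high_fracs,low_thrs,min_ibs grid values (window seconds,
#'   opening threshold as a fraction of the unit count, closing threshold in
#'   spikes/window, minimum interburst seconds).
#' @param step detector step used during tuning, seconds.
#' @return `list(window, high_thr, low_thr, min_interburst, score)`.
#' @export
auto_tune_thresholds <- function(recording,
                                 windows = c(0.005, 0.01, 0.02, 0.05, 0.1),
                                 high_fracs = c(0.1, 0.2, 0.25, 0.35),
                                 low_thrs = c(1, 2, 4),
                                 min_ibs = c(0.1, 0.2),
                                 step = 0.002) {
  stopifnot(inherits(recording, "mea_recording"))
  if (recording$duration < 600) stopf("auto-tuning needs at least 10 minutes of recording")
  pooled <- sort(unlist(recording$spikes, use.names = FALSE))
  if (!length(pooled)) stopf("no activity to tune on")
  n_units <- length(recording$spikes)

  bin <- 0.05
  edges <- seq(0, recording$duration + bin, by = bin)
  counts <- tabulate(findInterval(pooled, edges), length(edges) - 1L)
  sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  ref <- as.numeric(sm) > 0.05 * stats::quantile(sm, 0.99, names = FALSE)

  mask_from <- function(up) {
    m <- logical(length(counts))
    if (nrow(up)) {
      i1 <- pmax(1L, floor(up$start / bin) + 1L)
      i2 <- pmin(length(counts), ceiling(up$end / bin))
      for (k in seq_len(nrow(up))) m[i1[k]:i2[k]] <- TRUE
    }
    m
  }

  best <- NULL
  for (w in windows) for (hf in high_fracs) for (lo in low_thrs) for (mi in min_ibs) {
    hi <- max(hf * n_units, lo)
    up <- detect_upstates(recording, window = w, high_thr = hi, low_thr = lo,
                          min_interburst = mi, step = step)
    m <- mask_from(up)
    inter <- sum(m & ref); uni <- sum(m | ref)
    score <- if (uni > 0) inter / uni else 0
    if (is.null(best) || score > best$score + 1e-12) {
      best <- list(window = w, high_thr = hi, low_thr = lo,
                   min_interburst = mi, score = score)
    }
  }
  best
}
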