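#' Fano factor of windowed spike counts
#'
#' Variance-to-mean ratio of spike counts in consecutive non-overlapping
#' windows across a time segment: 1 for Poisson firing, 0 for a perfectly
#' regular train counted at an integer multiple of its period, above 1 for
#' bursty firing. Unbiased sample variance is used.
#'
#' @param spike_times numeric vector of spike times, seconds.
#' @param segment `c(start, end)` of the counting segment, seconds; must span
#'   at least 2 counting windows (>= 10 recommended for a stable estimate).
#' @param count_window counting-window length, seconds (default 100 ms).
#' @return The Fano factor, or `NA` (flagged missing) when the mean count is 0.
#' @export
fano_factor <- function(spike_times, segment, count_window = 0.1) {
  if (length(segment) != 2 || diff(segment) < 2 * count_window)
    stopf("segment must span at least 2 counting windows")
  nb <- floor(diff(segment) / count_window + 1e-9)
  edges <- segment[1] + count_window * (0:nb)
  tms <- spike_times[spike_times >= segment[1] & spike_times < edges[nb + 1]]
  counts <- tabulate(findInterval(tms, edges), nb)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::var(counts) / m
}

#' Autocorrelogram of a spike train
#'
#' Histogram of all ordered pairwise lags in `(0, span]`, in bins of `bin`
#' seconds, normalized by the number of spikes. The zero-lag (self) count is
#' excluded. Trains with fewer than two spikes give a zero vector flagged via
#' `attr(, "flagged")`.
#'
#' @param spike_times sorted numeric vector of spike times, seconds.
#' @param bin lag bin width, seconds.
#' @param span maximal lag, seconds.
#' @return Numeric vector of `span / bin` normalized lag counts; bin k covers
#'   `((k-1) * bin, k * bin]`.
#' @export
autocorrelogram <- function(spike_times, bin = 0.005, span = 0.5) {
  nb <- as.integer(round(span / bin))
  out <- numeric(nb)
  n <- length(spike_times)
  if (n < 2) {
    attr(out, "flagged") <- TRUE
    return(out)
  }
  if (is.unsorted(spike_times)) stopf("spike_times must be sorted")
  hi <- findInterval(spike_times + span + 1e-12, spike_times)
  npairs <- hi - seq_len(n)
  npairs[npairs < 0] <- 0L
  i <- rep(seq_len(n), npairs)
  j <- i + sequence(npairs)
  lags <- spike_times[j] - spike_times[i]
  lags <- lags[lags > 0 & lags <= span + 1e-12]
  idx <- pmin(nb, as.integer(ceiling(lags / bin - 1e-9)))
  out <- tabulate(idx, nb) / n
  attr(out, "flagged") <- FALSE
  out
}

#' Per-unit burst statistics in a time segment
#'
#' Computes, for every unit, the burst-level statistics over the up-states
#' whose onset falls inside the segment: mean burst duration (BD) and spike
#' number (SN) over the unit's burst annotations, overall spike rate (SR =
#' segment spikes / segment length), intra-burst spike rate (IBSR = total SN /
#' total per-unit BD), mean onset-to-onset inter-burst interval over the
#' up-states the unit engages in, and the Fano factor of 100 ms spike counts.
#' Units engaging no burst in the segment are flagged missing (NA statistics),
#' not zero.
#'
#' @param recording an `mea_recording`.
#' @param upstates detected up-states.
#' @param annotations output of [annotate_unit_bursts()]; computed if `NULL`.
#' @param segment `c(start, end)` in seconds; default the whole recording.
#' @param ff_window Fano-factor counting window, seconds.
#' @return Data frame with one row per unit: `unit_id`, `n_bursts`, `bd_mean`,
#'   `sn_mean`, `sr`, `ibsr`, `ibi_mean`, `ff`, `missing`.
#' @export
segment_stats <- function(recording, upstates, annotations = NULL,
                          segment = NULL, ff_window = 0.1) {
  stopifnot(inherits(recording, "mea_recording"))
  if (is.null(segment)) segment <- c(0, recording$duration)
  if (segment[1] < 0 || segment[2] > recording$duration + 1e-9 ||
      segment[1] >= segment[2])
    stopf("segment must lie within the recording")
  if (is.null(annotations)) annotations <- annotate_unit_bursts(upstates, recording)
  in_seg <- which(upstates$start >= segment[1] & upstates$start < segment[2])
  ann <- annotations[annotations$upstate %in% in_seg, , drop = FALSE]
  seg_len <- diff(segment)
  rows <- lapply(names(recording$spikes), function(uid) {
    su <- recording$spikes[[uid]]
    sr <- sum(su >= segment[1] & su < segment[2]) / seg_len
    ff <- fano_factor(su, segment, ff_window)
    a <- ann[ann$unit_id == uid, , drop = FALSE]
    if (!nrow(a)) {
      return(data.frame(unit_id = uid, n_bursts = 0L, bd_mean = NA_real_,
                        sn_mean = NA_real_, sr = sr, ibsr = NA_real_,
                        ibi_mean = NA_real_, ff = ff, missing = TRUE,
                        stringsAsFactors = FALSE))
    }
    onsets <- upstates$start[a$upstate]
    data.frame(unit_id = uid, n_bursts = nrow(a), bd_mean = mean(a$bd_unit),
               sn_mean = mean(a$sn), sr = sr,
               ibsr = sum(a$sn) / sum(a$bd_unit),
               ibi_mean = if (nrow(a) >= 2) mean(diff(sort(onsets))) else NA_real_,
               ff = ff, missing = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spike-number time histogram of up-states
#'
#' Mean spike count per time bin relative to up-state onset, averaged across
#' the given up-states, for the spikes of a set of units (e.g. one class in one
#' network state). The histogram conserves counts: `sum(hist) * n_upstates`
#' equals the total number of the units' spikes inside the up-states.
#'
#' @param recording an `mea_recording`.
#' @param upstates the up-states to average over (pre-filtered to one state).
#' @param unit_ids units whose spikes are pooled (default all units).
#' @param bin bin width, seconds (default 0.1).
#' @param n_bins number of bins; default spans the longest up-state.
#' @return Numeric vector of mean spikes per bin, with `n_upstates` and `bin`
#'   attributes.
#' @export
sn_time_histogram <- function(recording, upstates, unit_ids = NULL, bin = 0.1,
                              n_bins = NULL) {
  stopifnot(inherits(recording, "mea_recording"))
  if (!nrow(upstates)) stopf("no up-states in the requested state")
  if (is.null(unit_ids)) unit_ids <- names(recording$spikes)
  if (is.null(n_bins)) n_bins <- max(1L, as.integer(ceiling(max(upstates$bd) / bin)))
  acc <- numeric(n_bins)
  for (uid in unit_ids) {
    su <- recording$spikes[[uid]]
    if (!length(su)) next
    for (b in seq_len(nrow(upstates))) {
      lo <- findInterval(upstates$start[b] - 1e-12, su)
      hi <- findInterval(upstates$end[b] + 1e-12, su)
      if (hi <= lo) next
      off <- su[(lo + 1L):hi] - upstates$start[b]
      idx <- pmin(n_bins, floor(off / bin) + 1L)
      acc <- acc + tabulate(idx, n_bins)
    }
  }
  out <- acc / nrow(upstates)
  attr(out, "n_upstates") <- nrow(upstates)
  attr(out, "bin") <- bin
  out
}
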