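as_durations <- function(x) {
  if (is.data.frame(x) && "bd" %in% names(x)) x$bd else as.numeric(x)
}

#' Burst-duration histogram with four normalizations
#'
#' Bins up-state durations into left-closed, right-open bins of `bin_width`
#' seconds (edges at integer multiples of the width; a duration exactly on an
#' edge falls in the upper bin) and computes the four normalizations used to
#' compare recordings of unequal length: raw event counts, total time spent in
#' up-states of each duration bin, fraction of events, and fraction of the
#' total recording time.
#'
#' @param upstates an `upstates` data frame or a numeric vector of durations
#'   (seconds).
#' @param total_record_time total recording duration, seconds.
#' @param bin_width bin width, seconds (default 0.25).
#' @param meta optional named list merged into the metadata.
#' @return A `bd_histogram`: `bin_edges`, `counts`, `time_per_bin`,
#'   `frac_events`, `frac_time`, `meta` (with `total_events`,
#'   `total_upstate_time`, `total_record_time`, `bin_width`). With no events
#'   the fraction columns are NA and flagged undefined.
#' @export
bd_histogram <- function(upstates, total_record_time, bin_width = 0.25,
                         meta = list()) {
  bds <- as_durations(upstates)
  if (bin_width <= 0) stopf("bin_width must be positive")
  if (any(bds <= 0)) stopf("burst durations must be positive")
  if (total_record_time < sum(bds))
    stopf("total_record_time (%.4g s) is less than the summed up-state time (%.4g s)",
          total_record_time, sum(bds))
  n <- length(bds)
  nb <- if (n) max(1L, as.integer(floor(max(bds) / bin_width)) + 1L) else 1L
  edges <- bin_width * (0:nb)
  idx <- pmin(nb, as.integer(floor(bds / bin_width)) + 1L) # left-closed bins
  counts <- tabulate(idx, nb)
  time_per_bin <- {
    tpb <- numeric(nb)
    if (n) for (k in seq_len(n)) tpb[idx[k]] <- tpb[idx[k]] + bds[k]
    tpb
  }
  frac_events <- if (n) counts / n else rep(NA_real_, nb)
  frac_time <- if (total_record_time > 0) time_per_bin / total_record_time else rep(NA_real_, nb)
  m <- c(list(total_events = n, total_upstate_time = sum(bds),
              total_record_time = total_record_time, bin_width = bin_width,
              undefined_fractions = (n == 0)), meta)
  structure(list(bin_edges = edges, counts = counts, time_per_bin = time_per_bin,
                 frac_events = frac_events, frac_time = frac_time, meta = m),
            class = "bd_histogram")
}

#' Pool burst-duration histograms across experiments
#'
#' Sums counts and up-state times bin-wise over experiments sharing the same
#' bin convention (zero-padding shorter histograms to the pooled range) and
#' returns the pooled histogram together with the per-experiment probability
#' (fraction-of-events) curves on the common support.
#'
#' @param hists list of `bd_histogram` objects with identical bin widths.
#' @return `list(pooled, probability, per_experiment)`: `pooled` is a
#'   `bd_histogram`; `probability` its fraction-of-events curve;
#'   `per_experiment` a matrix (bins x experiments) of the individual curves.
#' @export
pool_bd_histograms <- function(hists) {
  if (!length(hists)) stopf("no histograms to pool")
  widths <- vapply(hists, function(h) h$meta$bin_width, numeric(1))
  if (any(abs(widths - widths[1]) > 1e-9)) stopf("bin-width mismatch across histograms")
  nb <- max(vapply(hists, function(h) length(h$counts), integer(1)))
  pad <- function(v) c(v, rep(0, nb - length(v)))
  counts <- Reduce(`+`, lapply(hists, function(h) pad(h$counts)))
  tpb <- Reduce(`+`, lapply(hists, function(h) pad(h$time_per_bin)))
  total_events <- sum(vapply(hists, function(h) h$meta$total_events, numeric(1)))
  total_rec <- sum(vapply(hists, function(h) h$meta$total_record_time, numeric(1)))
  pooled <- structure(list(bin_edges = widths[1] * (0:nb),
                           counts = counts, time_per_bin = tpb,
                           frac_events = if (total_events > 0) counts / total_events else rep(NA_real_, nb),
                           frac_time = tpb / total_rec,
                           meta = list(total_events = total_events,
                                       total_upstate_time = sum(tpb),
                                       total_record_time = total_rec,
                                       bin_width = widths[1],
                                       n_experiments = length(hists))),
                      class = "bd_histogram")
  per_exp <- vapply(hists, function(h) {
    fe <- pad(h$frac_events)
    fe
  }, numeric(nb))
  list(pooled = pooled, probability = pooled$frac_events,
       per_experiment = matrix(per_exp, nrow = nb))
}

#' Probability of an up-state longer than a threshold
#'
#' Computed on the raw durations (not the binned histogram) to avoid bin-edge
#' artifacts: `count(bd > threshold) / total events`. In control cultures this
#' probability is of order 1e-5 at the conventional 15 s threshold; in
#' epileptiform cultures it is roughly two orders of magnitude larger.
#'
#' @param upstates an `upstates` data frame or numeric durations, seconds.
#' @param threshold duration threshold, seconds (default 15).
#' @return The probability.
#' @export
p_long_upstate <- function(upstates, threshold = 15) {
  bds <- as_durations(upstates)
  if (!length(bds)) stopf("no up-states: probability undefined")
  mean(bds > threshold)
}

#' Cumulative burst-duration distribution
#'
#' Nondecreasing step function from 0 to the number of events: the count of
#' up-states with duration not exceeding each observed duration. Used to
#' compare a network before and during drug application.
#'
#' @param upstates an `upstates` data frame or numeric durations, seconds.
#' @return Data frame with columns `duration` (sorted) and `cum_count`.
#' @export
cumulative_bd <- function(upstates) {
  bds <- sort(as_durations(upstates))
  data.frame(duration = bds, cum_count = seq_along(bds))
}

#' @export
print.bd_histogram <- function(x, ...) {
  cat(sprintf("<bd_histogram> %d events in %d bins of %.3g s (up-state time %.4g s / record %.4g s)\n",
              x$meta$total_events, length(x$counts), x$meta$bin_width,
              x$meta$total_upstate_time, x$meta$total_record_time))
  invisible(x)
}
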