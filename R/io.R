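#' Write a recording to a timestamp file
#'
#' Writes spike-sorted timestamps as a tab-separated file (`unit_id`,
#' `electrode_id`, `spike_time` in seconds with 6 decimals, time origin at
#' recording start) plus a JSON sidecar header (`<path>.json`) carrying the
#' recording id, duration, sampling rate, mode tag and preset. The format is
#' plain and diff-able; identical recordings produce byte-identical files.
#'
#' @param recording an `mea_recording`.
#' @param path output file path (sidecar written to `paste0(path, ".json")`).
#' @param recording_id identifier stored in the header.
#' @return `path`, invisibly.
#' @export
write_timestamps <- function(recording, path, recording_id = "recording") {
  stopifnot(inherits(recording, "mea_recording"))
  units <- recording$units
  hdr <- list(recording_id = recording_id,
              duration = recording$duration,
              sampling_rate = 40000,
              mode = recording$mode,
              preset = recording$mode,
              n_units = nrow(units),
              format = "meaburst-timestamps-v1")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  rows <- character(0)
  for (i in seq_len(nrow(units))) {
    tms <- recording$spikes[[units$unit_id[i]]]
    if (length(tms)) {
      rows <- c(rows, sprintf("%s\t%d\t%.6f", units$unit_id[i],
                              units$electrode_id[i], tms))
    }
  }
  con <- file(path, open = "wb") # binary mode: fixed \n line endings
  on.exit(close(con))
  writeLines(c("unit_id\telectrode_id\tspike_time", rows), con, sep = "\n")
  invisible(path)
}

#' Read a timestamp file
#'
#' Parses a file written by [write_timestamps()], validating the invariants of
#' the format: spike times sorted non-decreasing within each unit, no
#' duplicated (unit, time) pairs, and all times within `[0, duration]` of the
#' sidecar header. Violations are rejected with the offending unit and line
#' numbers.
#'
#' @param path file path (sidecar expected at `paste0(path, ".json")`).
#' @return An `mea_recording` (without simulation ground truth).
#' @export
read_timestamps <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (!file.exists(side)) stopf("missing sidecar header: %s", side)
  hdr <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(hdr$duration)) stopf("sidecar header lacks a duration")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "numeric"),
                           stringsAsFactors = FALSE)
  if (!identical(names(tab), c("unit_id", "electrode_id", "spike_time")))
    stopf("malformed timestamp file: expected columns unit_id, electrode_id, spike_time")
  line_no <- seq_len(nrow(tab)) + 1L # 1 header line
  bad <- which(!is.finite(tab$spike_time) | tab$spike_time < 0 |
                 tab$spike_time > hdr$duration + 1e-9)
  if (length(bad))
    stopf("spike time outside [0, duration] at line(s) %s",
          paste(utils::head(line_no[bad], 5), collapse = ", "))
  units <- unique(tab[, c("unit_id", "electrode_id")])
  if (anyDuplicated(units$unit_id))
    stopf("unit_id mapped to more than one electrode")
  spikes <- stats::setNames(rep(list(numeric(0)), nrow(units)), units$unit_id)
  for (uid in units$unit_id) {
    sel <- tab$unit_id == uid
    tms <- tab$spike_time[sel]
    if (is.unsorted(tms)) {
      first_bad <- which(diff(tms) < 0)[1] + 1L
      stopf("unsorted spike times for unit %s (line %d)", uid,
            line_no[sel][first_bad])
    }
    if (anyDuplicated(tms)) {
      dup <- which(duplicated(tms))[1]
      stopf("duplicate (unit, time) for unit %s (line %d)", uid, line_no[sel][dup])
    }
    spikes[[uid]] <- tms
  }
  units_df <- data.frame(unit_id = units$unit_id,
                         electrode_id = units$electrode_id,
                         true_class = rep(NA_character_, nrow(units)),
                         stringsAsFactors = FALSE)
  structure(list(units = units_df, spikes = spikes,
                 duration = as.numeric(hdr$duration),
                 mode = hdr$mode %||% NA_character_,
                 config = NULL,
                 truth = list(schedule = data.frame(start = numeric(0), bd = numeric(0)),
                              engaged = NULL, rate_mult = NULL, state = NULL,
                              intensity = NA_real_)),
            class = "mea_recording")
}

#' Write a burst-duration histogram to CSV
#'
#' Stores a [bd_histogram()] as CSV with one row per bin (`bin_left`,
#' `bin_right`, `count`, `time_in_bin`, `frac_events`, `frac_time`; bins are
#' left-closed, right-open) plus a JSON sidecar with the metadata (bin width
#' and the event/time totals).
#'
#' @param hist a `bd_histogram`.
#' @param path output CSV path (sidecar at `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "bd_histogram"))
  nb <- length(hist$counts)
  df <- data.frame(bin_left = hist$bin_edges[seq_len(nb)],
                   bin_right = hist$bin_edges[seq_len(nb) + 1L],
                   count = hist$counts,
                   time_in_bin = hist$time_per_bin,
                   frac_events = hist$frac_events,
                   frac_time = hist$frac_time)
  jsonlite::write_json(hist$meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","),
               do.call(sprintf, c(list("%.10g,%.10g,%.10g,%.10g,%.10g,%.10g"),
                                  as.list(df)))), con, sep = "\n")
  invisible(path)
}

#' Read a burst-duration histogram from CSV
#'
#' Inverse of [write_histogram()]; round-trips bin edges and all four
#' normalization columns exactly (to write precision). Rejects negative counts
#' and bin edges inconsistent with the declared bin width.
#'
#' @param path CSV path.
#' @return A `bd_histogram`.
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  df <- utils::read.delim(path, header = TRUE, sep = ",",
                          colClasses = "numeric", stringsAsFactors = FALSE)
  need <- c("bin_left", "bin_right", "count", "time_in_bin", "frac_events", "frac_time")
  if (!all(need %in% names(df))) stopf("malformed histogram file: missing columns")
  if (any(df$count < 0)) stopf("negative count at row %d", which(df$count < 0)[1])
  width <- meta$bin_width %||% (df$bin_right[1] - df$bin_left[1])
  if (any(abs(df$bin_right - df$bin_left - width) > 1e-9))
    stopf("bin edges inconsistent with declared bin width %.6g", width)
  if (any(abs(df$bin_left / width - round(df$bin_left / width)) > 1e-6))
    stopf("bin edges are not multiples of the bin width %.6g", width)
  structure(list(bin_edges = c(df$bin_left, df$bin_right[nrow(df)]),
                 counts = as.numeric(df$count),
                 time_per_bin = df$time_in_bin,
                 frac_events = df$frac_events,
                 frac_time = df$frac_time,
                 meta = as.list(meta)),
            class = "bd_histogram")
}
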