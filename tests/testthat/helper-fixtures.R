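# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

wt_rec_10min <- function() get_fixture("wt10", function() {
  clean_recording(simulate_recording(network_config("WT", seed = 11L), 600))
})

wt_ups_10min <- function() get_fixture("wt10_ups", function() {
  detect_upstates(wt_rec_10min())
})

wt_rec_1h <- function() get_fixture("wt1h", function() {
  clean_recording(simulate_recording(network_config("WT", seed = 12L), 3600))
})

wt_ups_1h <- function() get_fixture("wt1h_ups", function() {
  detect_upstates(wt_rec_1h())
})

wt_stats_1h <- function() get_fixture("wt1h_stats", function() {
  segment_stats(wt_rec_1h(), wt_ups_1h())
})

wt_classes_1h <- function() get_fixture("wt1h_classes", function() {
  classify_units(wt_stats_1h())
})

wt_states_1h <- function() get_fixture("wt1h_states", function() {
  classify_states(wt_rec_1h(), wt_ups_1h())
})

# Hand-built recording from a named list of spike-time vectors.
make_recording <- function(spikes, duration, electrode_id = NULL) {
  n <- length(spikes)
  ids <- names(spikes) %||% sprintf("u%03d", seq_len(n))
  names(spikes) <- ids
  units <- data.frame(unit_id = ids,
                      electrode_id = electrode_id %||% ceiling(seq_len(n) / 2),
                      true_class = NA_character_, stringsAsFactors = FALSE)
  structure(list(units = units, spikes = lapply(spikes, sort),
                 duration = duration, mode = "custom", config = NULL,
                 truth = list(schedule = data.frame(start = numeric(0),
                                                    bd = numeric(0)),
                              engaged = NULL, rate_mult = NULL, state = NULL,
                              intensity = NA_real_)),
            class = "mea_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force sequential refractory scan (independent of the compiled path).
oracle_refractory <- function(times, refractory = 0.0025) {
  kept <- numeric(0)
  last <- -Inf
  for (x in times) {
    if (x - last >= refractory) {
      kept <- c(kept, x)
      last <- x
    }
  }
  kept
}

# Brute-force up-state detector: explicit 1 ms-step state machine with naive
# per-window spike counting, boundaries snapped to spikes.
oracle_detect <- function(recording, window = 0.01, high_thr, low_thr = 2,
                          min_interburst = 0.1, step = 0.001) {
  pooled <- sort(unlist(recording$spikes, use.names = FALSE))
  t <- seq(0, max(recording$duration - window, 0), by = step)
  cnt <- vapply(t, function(s) sum(pooled > s & pooled <= s + window), numeric(1))
  L <- ceiling(min_interburst / step)
  in_up <- FALSE; low_run <- 0L; open_i <- NA_integer_
  starts <- numeric(0); ends <- numeric(0)
  close_at <- function(open_i, close_i) {
    t_open <- t[open_i]
    t_close <- t[close_i] + window
    span <- pooled[pooled > t_open & pooled <= t_close + 1e-12]
    if (length(span) >= 2 && max(span) > min(span)) {
      starts <<- c(starts, min(span)); ends <<- c(ends, max(span))
    }
  }
  last_active <- NA_integer_
  for (i in seq_along(cnt)) {
    if (!in_up) {
      if (cnt[i] >= high_thr) { in_up <- TRUE; open_i <- i; low_run <- 0L; last_active <- i }
    } else {
      if (cnt[i] < low_thr) {
        low_run <- low_run + 1L
        if (low_run >= L) {
          close_at(open_i, i - L)
          in_up <- FALSE; low_run <- 0L
        }
      } else {
        low_run <- 0L; last_active <- i
      }
    }
  }
  if (in_up) close_at(open_i, length(cnt))
  data.frame(start = starts, end = ends, bd = ends - starts)
}
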