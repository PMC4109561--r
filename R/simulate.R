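#' Sample an up-state schedule
#'
#' Draws the alternating up-state/down-state timeline of a simulated recording:
#' onset-to-onset gaps are exponential with mean `config$ibi_mean`, burst
#' durations come from the short/long mixture (see [sample_burst_durations()]),
#' and consecutive bursts are kept disjoint by at least `config$min_down`
#' seconds of silent down-state. Only bursts entirely inside
#' `[0, total_duration]` are returned.
#'
#' @param config an [network_config()] object.
#' @param total_duration recording length in seconds (> 0 for a non-trivial
#'   schedule; 0 or a duration shorter than one mean inter-burst interval gives
#'   an empty schedule with a warning).
#' @param seed RNG seed; defaults to a stream derived from `config$seed`.
#' @return A `data.frame` with columns `start` and `bd` (seconds), with the
#'   requested duration in `attr(, "total_duration")`.
#' @export
sample_upstate_schedule <- function(config, total_duration,
                                    seed = derive_seed(config$seed, 101L)) {
  validate_network_config(config)
  if (!is_scalar_num(total_duration) || total_duration < 0)
    stopf("total_duration must be a non-negative number")
  empty <- data.frame(start = numeric(0), bd = numeric(0))
  attr(empty, "total_duration") <- total_duration
  if (total_duration == 0) return(empty)
  if (total_duration < config$ibi_mean)
    warnf("duration (%.3g s) is shorter than one mean inter-burst interval (%.3g s); schedule may be empty",
          total_duration, config$ibi_mean)

  n_try <- as.integer(ceiling(total_duration / config$ibi_mean * 1.5) + 25)
  res <- with_seed(seed, {
    starts <- numeric(0); bds <- numeric(0)
    t_last <- 0; bd_last <- 0; first <- TRUE; done <- FALSE
    while (!done) {
      gaps <- stats::rexp(n_try, rate = 1 / config$ibi_mean)
      bd_new <- sample_burst_durations(config, n_try, seed = NULL)
      for (i in seq_len(n_try)) {
        # onset-to-onset gap, clamped so the previous burst plus a minimum
        # down-state always fits before the next onset
        step_i <- if (first) gaps[i] else max(gaps[i], bd_last + config$min_down)
        t_start <- t_last + step_i
        first <- FALSE
        if (t_start > total_duration) { done <- TRUE; break }
        if (t_start + bd_new[i] <= total_duration) {
          starts <- c(starts, t_start); bds <- c(bds, bd_new[i])
        }
        t_last <- t_start; bd_last <- bd_new[i]
      }
    }
    list(starts = starts, bds = bds)
  })
  finish_schedule(res$starts, res$bds, total_duration)
}

finish_schedule <- function(starts, bds, total_duration) {
  out <- data.frame(start = starts, bd = bds)
  attr(out, "total_duration") <- total_duration
  out
}

# Expected refractory-thinned spike count for an exponentially decaying
# envelope: intensity lambda(t) = A * exp(-t / tau) on [0, bd], dead time r.
# The equilibrium dead-time correction lambda / (1 + lambda * r) integrates in
# closed form.
envelope_mass_deadtime <- function(A, bd, tau, r) {
  ar <- A * r
  (tau / r) * (log1p(ar) - log1p(ar * exp(-bd / tau)))
}

# Raw (no dead time) envelope mass, used to draw the Poisson counts that are
# then thinned by the sequential refractory scan.
envelope_mass_raw <- function(A, bd, tau) {
  A * tau * (1 - exp(-bd / tau))
}

# Mean of a Poisson(m) count conditioned on being >= 1 (an engaged unit fires
# at least one spike by definition of participation).
cond_mean <- function(m) ifelse(m < 1e-9, 1, m / (1 - exp(-m)))

#' Generate spike trains for a scheduled recording
#'
#' Realizes a [sample_upstate_schedule()] as per-unit spike trains. For each
#' up-state, excitatory units are engaged with the probability of the burst's
#' state (its duration quartile within the schedule), inhibitory units are
#' always engaged, and each engaged unit fires an inhomogeneous Poisson train
#' under an envelope with instantaneous rise and exponential decay (decay
#' constant `envelope_decay_frac * bd`), conditioned on at least one spike.
#' A sequential scan enforces the 2.5 ms refractory period, and the global
#' intensity is calibrated (by root finding on the dead-time-corrected,
#' participation-conditioned expectation) so the realized array-aggregate rate
#' matches `config$target_array_rate`. Down-states are silent.
#'
#' @param schedule output of [sample_upstate_schedule()] (non-overlapping).
#' @param config the [network_config()] used for the schedule.
#' @param seed RNG seed; defaults to a stream derived from `config$seed`.
#' @return An object of class `mea_recording`: a list with `units` (data frame
#'   of `unit_id`, `electrode_id`, `true_class`), `spikes` (named list of
#'   sorted spike-time vectors), `duration`, `mode`, `config`, and a `truth`
#'   list (schedule, engagement matrix, per-unit rate multipliers, state
#'   proxies, calibrated intensity) for simulation audits.
#' @export
generate_spikes <- function(schedule, config, seed = derive_seed(config$seed, 202L)) {
  validate_network_config(config)
  if (!is.data.frame(schedule) || !all(c("start", "bd") %in% names(schedule)))
    stopf("schedule must be a data.frame with columns start, bd")
  if (nrow(schedule) > 1) {
    ends <- schedule$start + schedule$bd
    if (any(schedule$start[-1] < ends[-nrow(schedule)] - 1e-12))
      stopf("schedule has overlapping up-states")
  }
  total_duration <- attr(schedule, "total_duration") %||%
    (if (nrow(schedule)) max(schedule$start + schedule$bd) else 0)

  n_exc <- config$n_excitatory; n_inh <- config$n_inhibitory
  n <- n_exc + n_inh
  unit_id <- sprintf("u%03d", seq_len(n))
  true_class <- rep(c("excitatory", "inhibitory"), c(n_exc, n_inh))
  # two units per electrode, classes interleaved across electrodes
  n_elec <- ceiling(n / 2)
  electrode_id <- ((seq_len(n) - 1L) %% n_elec) + 1L
  units <- data.frame(unit_id = unit_id, electrode_id = electrode_id,
                      true_class = true_class, stringsAsFactors = FALSE)

  spikes <- stats::setNames(rep(list(numeric(0)), n), unit_id)
  B <- nrow(schedule)
  if (B == 0) {
    return(structure(list(units = units, spikes = spikes,
                          duration = total_duration, mode = config$mode,
                          config = config,
                          truth = list(schedule = schedule,
                                       engaged = matrix(FALSE, n, 0),
                                       rate_mult = rep(1, n),
                                       state = integer(0),
                                       intensity = NA_real_)),
                     class = "mea_recording"))
  }

  bd <- schedule$bd; onset <- schedule$start
  tau <- config$envelope_decay_frac * bd
  r <- config$refractory

  with_seed(seed, {
    w <- exp(stats::rnorm(n, 0, config$rate_sdlog)) *
      ifelse(true_class == "inhibitory", config$inh_rate_mult, 1)

    # state proxy at generation time: duration quartile within this schedule
    qs <- stats::quantile(bd, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    state <- findInterval(bd, qs, left.open = TRUE) + 1L

    p_eng <- config$engagement_by_state[state]
    engaged <- matrix(FALSE, n, B)
    engaged[true_class == "inhibitory", ] <- TRUE
    if (n_exc > 0) {
      engaged[true_class == "excitatory", ] <-
        matrix(stats::runif(n_exc * B), n_exc, B) <=
        matrix(p_eng, n_exc, B, byrow = TRUE)
    }

    idx <- which(engaged, arr.ind = TRUE)
    u <- idx[, 1L]; b <- idx[, 2L]
    target_total <- config$target_array_rate * total_duration

    expected_total <- function(A) {
      m <- envelope_mass_deadtime(A * w[u], bd[b], tau[b], r)
      sum(cond_mean(m))
    }
    lo <- 1e-9; hi <- 4 / r # near the absolute refractory ceiling
    if (expected_total(hi) < target_total)
      stopf("rate calibration infeasible: target %.3g Hz unreachable under the %.2g ms refractory period",
            config$target_array_rate, 1000 * r)
    if (expected_total(lo) >= target_total) {
      warnf("target array rate %.3g Hz is below the participation floor (one spike per engaged unit per up-state); using minimal intensity",
            config$target_array_rate)
      A <- lo
    } else {
      A <- stats::uniroot(function(a) expected_total(a) - target_total,
                          lower = lo, upper = hi, tol = 1e-7)$root
    }

    mu <- envelope_mass_raw(A * w[u], bd[b], tau[b])
    N <- stats::rpois(length(mu), mu)
    N[N == 0L] <- 1L # engagement means at least one spike
    uu <- rep(u, N); bb <- rep(b, N)
    uq <- stats::runif(length(uu))
    tt <- onset[bb] - tau[bb] * log(1 - uq * (1 - exp(-bd[bb] / tau[bb])))

    ord <- order(uu, tt)
    uu <- uu[ord]; tt <- tt[ord]
    keep <- refractory_keep_grouped(tt, as.integer(uu), r)
    uu <- uu[keep]; tt <- tt[keep]
    spk <- split(tt, factor(uu, levels = seq_len(n)))
    names(spk) <- unit_id
    spikes <- lapply(spk, as.numeric)

    structure(list(units = units, spikes = spikes, duration = total_duration,
                   mode = config$mode, config = config,
                   truth = list(schedule = schedule, engaged = engaged,
                                rate_mult = w, state = state, intensity = A)),
              class = "mea_recording")
  })
}

#' Expected spike count of a simulated recording
#'
#' The generator's own analytic expectation of the total spike count, i.e. the
#' dead-time-corrected, participation-conditioned envelope mass summed over all
#' engaged unit/up-state pairs. Used to audit spike-count conservation.
#'
#' @param recording an `mea_recording` produced by [generate_spikes()].
#' @return Expected total number of spikes.
#' @export
expected_spike_count <- function(recording) {
  stopifnot(inherits(recording, "mea_recording"))
  tr <- recording$truth
  if (!nrow(tr$schedule)) return(0)
  cfg <- recording$config
  idx <- which(tr$engaged, arr.ind = TRUE)
  bd <- tr$schedule$bd; tau <- cfg$envelope_decay_frac * bd
  m <- envelope_mass_deadtime(tr$intensity * tr$rate_mult[idx[, 1]],
                              bd[idx[, 2]], tau[idx[, 2]], cfg$refractory)
  sum(cond_mean(m))
}

#' Simulate a full synthetic MEA recording
#'
#' Convenience wrapper: samples an up-state schedule and generates the spike
#' trains (and optionally a waveform bank) in one call.
#'
#' @param config an [network_config()] object.
#' @param duration recording length, seconds.
#' @param waveforms if `TRUE`, attach a [generate_waveforms()] bank as
#'   `attr(, "waveforms")`.
#' @param ... passed to [generate_waveforms()].
#' @return An `mea_recording`.
#' @export
simulate_recording <- function(config, duration, waveforms = FALSE, ...) {
  sched <- sample_upstate_schedule(config, duration)
  rec <- generate_spikes(sched, config)
  if (waveforms) attr(rec, "waveforms") <- generate_waveforms(rec, ...)
  rec
}

#' @export
print.mea_recording <- function(x, ...) {
  n_spk <- sum(lengths(x$spikes))
  cat(sprintf("<mea_recording> %s, %d units on %d electrodes, %.4g s\n",
              x$mode, nrow(x$units), length(unique(x$units$electrode_id)),
              x$duration))
  cat(sprintf("  %d spikes (array rate %.3g Hz), %d scheduled up-states\n",
              n_spk, if (x$duration > 0) n_spk / x$duration else NA_real_,
              nrow(x$truth$schedule)))
  invisible(x)
}

# Parametric biphasic action-potential template on `n` samples (1.2 ms at
# 40 kHz): a negative trough followed by a slower positive afterwave.
wave_template <- function(amp, width, n = 48L) {
  s <- seq_len(n)
  -amp * exp(-((s - 14)^2) / (2 * width^2)) +
    0.35 * amp * exp(-((s - 27)^2) / (2 * (1.9 * width)^2))
}

#' Generate a waveform bank for a recording
#'
#' Attaches a waveform snippet (1.2 ms at 40 kHz, 48 samples) to every spike.
#' Each unit has a fixed template (units sharing an electrode get distinct
#' amplitudes and widths) plus additive Gaussian noise; templates do not depend
#' on the up-state a spike falls in. A fraction `contam_frac` of spikes are
#' contaminants emulating overlaps/partial captures: the unit's own template
#' scaled by a factor drawn from `U(1.6, 2.2)` or `U(0.25, 0.55)` (50/50).
#'
#' @param recording an `mea_recording` with at least one spike.
#' @param noise_sd additive Gaussian noise SD (template peak is ~1).
#' @param contam_frac per-spike contamination probability.
#' @param n_samples samples per snippet (48 = 1.2 ms at 40 kHz).
#' @param seed RNG seed; defaults to a stream derived from the recording seed.
#' @return Object of class `mea_waveforms`: per-unit list of `waveforms`
#'   (spikes x samples matrix), `spike_times`, and the ground-truth
#'   `contaminant` flags; templates stored in `attr(, "templates")`.
#' @export
generate_waveforms <- function(recording, noise_sd = 0.05, contam_frac = 0.05,
                               n_samples = 48L,
                               seed = derive_seed(recording$config$seed, 303L)) {
  stopifnot(inherits(recording, "mea_recording"))
  if (sum(lengths(recording$spikes)) == 0) stopf("recording has no spikes")
  if (contam_frac < 0 || contam_frac >= 1) stopf("contam_frac must be in [0, 1)")
  units <- recording$units
  n <- nrow(units)
  # deterministic per-unit templates; alternate amplitude within an electrode
  pos_in_elec <- stats::ave(seq_len(n), units$electrode_id, FUN = seq_along)
  amp <- ifelse(pos_in_elec == 1L, 1, 0.62)
  width <- 2.2 + 0.5 * ((seq_len(n) - 1L) %% 3L)
  templates <- lapply(seq_len(n), function(i) wave_template(amp[i], width[i], n_samples))
  names(templates) <- units$unit_id

  with_seed(seed, {
    bank <- lapply(seq_len(n), function(i) {
      tms <- recording$spikes[[units$unit_id[i]]]
      k <- length(tms)
      if (k == 0) {
        return(list(spike_times = numeric(0),
                    waveforms = matrix(numeric(0), 0, n_samples),
                    contaminant = logical(0)))
      }
      contaminant <- stats::runif(k) < contam_frac
      scale <- rep(1, k)
      if (any(contaminant)) {
        nc <- sum(contaminant)
        big <- stats::runif(nc) < 0.5
        sc <- numeric(nc)
        sc[big] <- stats::runif(sum(big), 1.6, 2.2)
        sc[!big] <- stats::runif(sum(!big), 0.25, 0.55)
        scale[contaminant] <- sc
      }
      wf <- outer(scale, templates[[i]])
      if (noise_sd > 0) wf <- wf + matrix(stats::rnorm(k * n_samples, 0, noise_sd), k, n_samples)
      list(spike_times = tms, waveforms = wf, contaminant = contaminant)
    })
    names(bank) <- units$unit_id
    structure(bank, class = "mea_waveforms", templates = templates,
              noise_sd = noise_sd, contam_frac = contam_frac)
  })
}
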