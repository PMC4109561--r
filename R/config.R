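#' Network configuration for the synthetic MEA generator
#'
#' Builds the parameter set that defines a simulated culture. Two presets are
#' provided. `"WT"` emulates a control neocortical network: short up-states
#' (truncated-exponential durations, mean 0.75 s), onset-to-onset inter-burst
#' intervals of ~19 s, an array-aggregate firing rate of 68 Hz, and a vanishing
#' probability (1e-5) of a long, seizure-like up-state. `"Mutant"` emulates a
#' hyperexcitable network carrying an epilepsy-linked nicotinic-receptor
#' subunit: the same short mode plus a rare (1e-3) long mode drawn uniformly
#' from 16-32 s, with no events at all in the 4-16 s gap.
#'
#' Burst durations are drawn from the mixture
#' `(1 - p_long) * TruncExp(bd_short_mean, upper = gap_range[1]) +
#'  p_long * Uniform(bd_long_range)`,
#' so `gap_range` is a hard support gap between the short and long modes.
#'
#' Excitatory units join an up-state with a probability that grows with the
#' network state (duration quartile at generation time), from
#' `engagement_by_state[1]` in the shortest-state bursts to 1 in the longest;
#' inhibitory units are always engaged. Inhibitory units fire `inh_rate_mult`
#' times faster than excitatory units and per-unit rates carry lognormal
#' heterogeneity (`rate_sdlog`), which produces the bimodal firing-statistics
#' pattern (FF, BD, SN, IBSR) that the unit classifier relies on.
#'
#' @param mode `"WT"` or `"Mutant"` preset.
#' @param ... named overrides of any preset field (see Details for fields).
#' @return An object of class `mea_config` (a validated named list).
#' @examples
#' cfg <- network_config("WT", seed = 42)
#' cfg$target_array_rate
#' @export
network_config <- function(mode = c("WT", "Mutant"), ...) {
  mode <- match.arg(mode)
  base <- list(
    mode               = mode,
    n_excitatory       = 52L,
    n_inhibitory       = 17L,
    ibi_mean           = 19,      # s, onset-to-onset
    bd_short_mean      = 0.75,    # s
    bd_long_range      = c(10, 32),
    p_long             = 1e-5,
    gap_range          = c(4, 10),
    target_array_rate  = 68,      # Hz, array-aggregate over the whole record
    engagement_by_state = c(0.6, 0.75, 0.9, 1.0),
    refractory         = 0.0025,  # s
    envelope_decay_frac = 0.3,    # decay constant as a fraction of burst duration
    inh_rate_mult      = 2.5,
    rate_sdlog         = 0.25,
    min_down           = 0.2,     # s, minimum silent down-state between bursts
    drug               = NULL,
    seed               = 1L
  )
  if (mode == "Mutant") {
    base$n_excitatory <- 63L
    base$n_inhibitory <- 15L
    base$ibi_mean     <- 24
    base$p_long       <- 1e-3
    base$bd_long_range <- c(16, 32)
    base$gap_range    <- c(4, 16)
    # mutant networks burst longer in every state: a representative mutant
    # record spends 2320 s in 1058 up-states (~2.2 s mean, bounded here by the
    # 4 s support gap), against 702 s in 1661 (~0.4 s) for its WT litter-mate
    base$bd_short_mean <- 1.8
    # within-burst firing intensity matches the control cultures (the spike
    # waveform and per-unit drive are genotype-independent); with ~4x longer
    # bursts at a 24 s IBI the array-aggregate rate is correspondingly higher
    base$target_array_rate <- 145
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown)) stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  base[names(dots)] <- dots
  cfg <- structure(base, class = "mea_config")
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  if (!inherits(cfg, "mea_config")) stopf("not an mea_config object")
  with(cfg, {
    if (!is_scalar_num(p_long) || p_long < 0 || p_long > 1) stopf("p_long must be in [0, 1]")
    if (n_excitatory < 0 || n_inhibitory < 0 || n_excitatory + n_inhibitory < 1)
      stopf("need at least one unit")
    if (length(gap_range) != 2 || gap_range[1] >= gap_range[2]) stopf("invalid gap_range")
    if (length(bd_long_range) != 2 || bd_long_range[1] >= bd_long_range[2])
      stopf("invalid bd_long_range")
    if (gap_range[2] > bd_long_range[1] + 1e-12)
      stopf("gap_range must lie between the short-mode support and bd_long_range")
    if (bd_short_mean <= 0 || bd_short_mean >= gap_range[1])
      stopf("bd_short_mean must be positive and below the gap lower bound")
    if (length(engagement_by_state) != 4 || any(diff(engagement_by_state) < -1e-12) ||
        any(engagement_by_state < 0 | engagement_by_state > 1))
      stopf("engagement_by_state must be 4 nondecreasing probabilities")
    if (ibi_mean <= 0 || target_array_rate <= 0 || refractory <= 0)
      stopf("ibi_mean, target_array_rate and refractory must be positive")
    if (envelope_decay_frac <= 0 || envelope_decay_frac > 1)
      stopf("envelope_decay_frac must be in (0, 1]")
    if (min_down <= 0) stopf("min_down must be positive")
  })
  invisible(cfg)
}

#' Pharmacological perturbation of a network configuration
#'
#' Describes a bath-applied drug as a Hill inhibition of firing,
#' `rate_scale = 1 / (1 + (C / IC50)^hill)`, plus a multiplicative suppression
#' of the long-up-state probability (`long_mode_scale`). Defaults model the
#' compounds used on these cultures: carbamazepine (CBZ) blocks firing with an
#' IC50 of 49 uM in WT networks and 10 uM in Mutant networks and extinguishes
#' the long mode on a threshold-linear ramp (gone at and beyond the IC50:
#' seizure-like events disappear before firing does); gabazine, penicillin-G
#' and midazolam mildly depress firing and abolish the long mode.
#'
#' @param name one of `"CBZ"`, `"gabazine"`, `"penicillinG"`, `"midazolam"`.
#' @param concentration bath concentration, molar. Must be non-negative.
#' @param ic50 half-inhibition concentration, molar. `NULL` uses the per-drug
#'   (and, for CBZ, per-genotype) default at [apply_drug()] time.
#' @param hill Hill coefficient (> 0).
#' @param long_mode_scale multiplier on `p_long` in `[0, 1]`, or `NULL` for the
#'   drug default (threshold-linear ramp for CBZ; 0 for the GABAergic
#'   modulators).
#' @return An object of class `mea_drug`.
#' @export
drug_effect <- function(name = c("CBZ", "gabazine", "penicillinG", "midazolam"),
                        concentration, ic50 = NULL, hill = 1,
                        long_mode_scale = NULL) {
  name <- match.arg(name)
  if (!is_scalar_num(concentration) || concentration < 0)
    stopf("concentration must be a non-negative number (molar)")
  if (!is.null(ic50) && (!is_scalar_num(ic50) || ic50 <= 0)) stopf("ic50 must be > 0")
  if (!is_scalar_num(hill) || hill <= 0) stopf("hill must be > 0")
  if (!is.null(long_mode_scale) &&
      (!is_scalar_num(long_mode_scale) || long_mode_scale < 0 || long_mode_scale > 1))
    stopf("long_mode_scale must be in [0, 1]")
  structure(list(name = name, concentration = concentration, ic50 = ic50,
                 hill = hill, long_mode_scale = long_mode_scale),
            class = "mea_drug")
}

# Default IC50 (molar) by drug and culture genotype.
default_ic50 <- function(name, mode) {
  switch(name,
         CBZ         = if (identical(mode, "Mutant")) 10e-6 else 49e-6,
         gabazine    = 5e-6,
         penicillinG = 2e-3,
         midazolam   = 20e-9)
}

#' Apply a drug effect to a network configuration
#'
#' Returns a new configuration in which the target array firing rate is scaled
#' by the Hill inhibition factor and the long-up-state probability `p_long` is
#' scaled by the drug's `long_mode_scale` (for CBZ, by the same Hill factor:
#' under CBZ both the number and the duration of seizure-like events fall).
#' The input configuration is not modified.
#'
#' @param config an [network_config()] object.
#' @param drug an [drug_effect()] object.
#' @return A new `mea_config` with the drug recorded in `$drug`.
#' @export
apply_drug <- function(config, drug) {
  validate_network_config(config)
  if (!inherits(drug, "mea_drug")) stopf("drug must be a drug_effect() object")
  if (drug$concentration < 0) stopf("negative concentration")
  ic50 <- drug$ic50 %||% default_ic50(drug$name, config$mode)
  rate_scale <- 1 / (1 + (drug$concentration / ic50)^drug$hill)
  # CBZ suppresses the long mode more steeply than overall firing: a
  # seizure-like up-state needs sustained reverberation, which collapses
  # entirely once firing falls to half of control. Threshold-linear ramp:
  # full long mode at C = 0, extinguished at and beyond the IC50.
  long_scale <- drug$long_mode_scale %||%
    (if (drug$name == "CBZ") max(0, 2 * rate_scale - 1) else 0)
  if (drug$concentration == 0) { # identity: no block, no long-mode suppression
    rate_scale <- 1
    long_scale <- 1
  }
  out <- config
  out$target_array_rate <- config$target_array_rate * rate_scale
  out$p_long <- config$p_long * long_scale
  out$drug <- list(name = drug$name, concentration = drug$concentration,
                   ic50 = ic50, hill = drug$hill,
                   rate_scale = rate_scale, long_mode_scale = long_scale)
  out
}

#' Sample burst durations from a configuration's mixture distribution
#'
#' Draws from the short/long burst-duration mixture that the up-state scheduler
#' uses: with probability `1 - p_long` a truncated exponential (mean
#' `bd_short_mean`, support `(0, gap_range[1]]`), otherwise a uniform draw from
#' `bd_long_range`.
#'
#' @param config an [network_config()] object.
#' @param n number of draws.
#' @param seed RNG seed; defaults to a stream derived from `config$seed`.
#'   `NULL` draws from the current RNG stream.
#' @return Numeric vector of `n` burst durations (seconds).
#' @export
sample_burst_durations <- function(config, n, seed = derive_seed(config$seed, 11L)) {
  validate_network_config(config)
  if (n <= 0) return(numeric(0))
  draw <- function() {
    long <- stats::runif(n) < config$p_long
    out <- numeric(n)
    # inverse-CDF draw from an exponential truncated to (0, upper], with the
    # scale chosen so the *truncated* mean equals bd_short_mean
    upper <- config$gap_range[1]
    m <- trunc_exp_scale(config$bd_short_mean, upper)
    u <- stats::runif(n)
    out[!long] <- -m * log(1 - u[!long] * (1 - exp(-upper / m)))
    out[long] <- stats::runif(sum(long), config$bd_long_range[1], config$bd_long_range[2])
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Scale parameter of an exponential truncated to (0, upper] whose mean equals
# `target`. The truncated mean is m - upper * exp(-upper/m) / (1 - exp(-upper/m)).
trunc_exp_scale <- function(target, upper) {
  if (target >= upper / 2) stopf("truncated mean must be below upper/2")
  tmean <- function(m) m - upper * exp(-upper / m) / (1 - exp(-upper / m))
  stats::uniroot(function(m) tmean(m) - target,
                 lower = target, upper = 2 * target, extendInt = "upX",
                 tol = 1e-10)$root
}

#' @export
print.mea_config <- function(x, ...) {
  cat(sprintf("<mea_config> %s preset: %d exc + %d inh units\n",
              x$mode, x$n_excitatory, x$n_inhibitory))
  cat(sprintf("  IBI %.3g s | short BD mean %.3g s | p_long %.3g | long range [%g, %g] s\n",
              x$ibi_mean, x$bd_short_mean, x$p_long,
              x$bd_long_range[1], x$bd_long_range[2]))
  cat(sprintf("  target array rate %.3g Hz | refractory %.2g ms | seed %s\n",
              x$target_array_rate, 1000 * x$refractory, format(x$seed)))
  if (!is.null(x$drug)) {
    cat(sprintf("  drug: %s %.3g uM (rate scale %.3g, long-mode scale %.3g)\n",
                x$drug$name, 1e6 * x$drug$concentration,
                x$drug$rate_scale, x$drug$long_mode_scale))
  }
  invisible(x)
}
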