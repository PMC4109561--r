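#' Normalized dose-response curve from recordings
#'
#' Computes the array-aggregate spike rate of each recording (total spikes /
#' duration) and normalizes by the control (zero-concentration) rate.
#'
#' @param recordings list of `mea_recording` objects, one per concentration.
#' @param concentrations matching numeric concentrations (same units
#'   throughout, e.g. molar); at least one must be 0 (the control) and at
#'   least 3 must be distinct.
#' @return `data.frame(concentration, rate, normalized_rate)` in input order.
#' @export
dose_response_curve <- function(recordings, concentrations) {
  if (length(recordings) != length(concentrations))
    stopf("recordings and concentrations must match")
  if (!any(concentrations == 0)) stopf("need a control (concentration 0) recording")
  if (length(unique(concentrations)) < 3) stopf("need at least 3 distinct concentrations")
  rate <- vapply(recordings, function(r) {
    stopifnot(inherits(r, "mea_recording"))
    sum(lengths(r$spikes)) / r$duration
  }, numeric(1))
  r0 <- mean(rate[concentrations == 0])
  if (r0 <= 0) stopf("control firing rate is zero; cannot normalize")
  data.frame(concentration = concentrations, rate = rate,
             normalized_rate = rate / r0)
}

hill_rate <- function(conc, ic50, hill) 1 / (1 + (conc / ic50)^hill)

#' Fit a two-parameter Hill inhibition curve
#'
#' Least-squares fit of `rate = 1 / (1 + (C / IC50)^h)` (top fixed at 1,
#' bottom at 0) to normalized firing rates. A full four-parameter logistic
#' would be under-determined at the 3-6 concentrations of a typical MEA drug
#' series. Deterministic multi-start (Hill slope started at 0.5, 1 and 2;
#' IC50 at the concentration closest to half block), best residual wins.
#'
#' @param concentrations numeric, same unit as the desired IC50; must bracket
#'   half-inhibition (some normalized rate below 0.5).
#' @param normalized_rates rates as fractions of control.
#' @return Object of class `dose_response`: `ic50`, `hill`, `residual`,
#'   `concentrations`, `normalized_rates`, `fitted`.
#' @export
fit_ic50 <- function(concentrations, normalized_rates) {
  if (length(concentrations) != length(normalized_rates))
    stopf("concentrations and rates must match")
  pos <- concentrations > 0
  if (length(unique(concentrations[pos])) < 3)
    stopf("need at least 3 distinct positive concentrations")
  if (min(normalized_rates) >= 0.5)
    stopf("no rate falls below half of control: extend the concentration range to bracket the IC50")
  sse <- function(par) {
    f <- hill_rate(concentrations, exp(par[1]), exp(par[2]))
    sum((normalized_rates - f)^2)
  }
  start_ic50 <- concentrations[pos][which.min(abs(normalized_rates[pos] - 0.5))]
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- try(stats::optim(c(log(start_ic50), log(h0)), sse, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-15) best <- fit
  }
  if (is.null(best)) stopf("Hill fit failed")
  structure(list(ic50 = exp(best$par[1]), hill = exp(best$par[2]),
                 residual = best$value,
                 concentrations = concentrations,
                 normalized_rates = normalized_rates,
                 fitted = hill_rate(concentrations, exp(best$par[1]),
                                    exp(best$par[2]))),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> IC50 = %.4g, Hill slope = %.3g (SSE %.3g, %d concentrations)\n",
              x$ic50, x$hill, x$residual, length(x$concentrations)))
  invisible(x)
}

#' Compare up-state durations before and during a drug
#'
#' The pre/post workflow of a wash-in experiment: cumulative burst-duration
#' curves for both conditions, counts of long (seizure-like) events above the
#' given thresholds, and a Kruskal-Wallis p-value on the raw durations.
#'
#' @param control_upstates,drug_upstates `upstates` data frames (or numeric
#'   durations) detected with identical detector settings.
#' @param long_thresholds duration thresholds (seconds) for long-event counts.
#' @return `list(cumulative_control, cumulative_drug, long_counts, kw)`.
#' @export
compare_pre_post <- function(control_upstates, drug_upstates,
                             long_thresholds = c(8, 15)) {
  bd_c <- as_durations(control_upstates)
  bd_d <- as_durations(drug_upstates)
  long_counts <- data.frame(
    threshold = long_thresholds,
    control = vapply(long_thresholds, function(th) sum(bd_c > th), numeric(1)),
    drug = vapply(long_thresholds, function(th) sum(bd_d > th), numeric(1)))
  kw <- if (length(bd_c) >= 2 && length(bd_d) >= 2) {
    if (identical(sort(bd_c), sort(bd_d))) {
      list(statistic = 0, p.value = 1, df = 1, method = "identical samples")
    } else kruskal_wallis(list(control = bd_c, drug = bd_d))
  } else list(statistic = NA_real_, p.value = NA_real_, df = NA, method = "insufficient data")
  list(cumulative_control = cumulative_bd(bd_c),
       cumulative_drug = cumulative_bd(bd_d),
       long_counts = long_counts, kw = kw)
}
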