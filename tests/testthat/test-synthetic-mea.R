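test_that("config presets and validation enforce the documented invariants", {
  wt <- network_config("WT")
  expect_identical(wt$n_excitatory, 52L)
  expect_identical(wt$n_inhibitory, 17L)
  mut <- network_config("Mutant")
  expect_identical(mut$n_excitatory, 63L)
  expect_identical(mut$n_inhibitory, 15L)
  expect_equal(mut$gap_range, c(4, 16))
  expect_equal(mut$bd_long_range, c(16, 32))
  expect_error(network_config("WT", p_long = 2), "p_long")
  expect_error(network_config("WT", gap_range = c(4, 20)), "gap_range")
  expect_error(network_config("WT", engagement_by_state = c(0.9, 0.6, 0.7, 1)),
               "nondecreasing")
})

test_that("burst-duration mixture has the configured support and mean", {
  # degenerate input
  expect_identical(sample_burst_durations(network_config("WT"), 0), numeric(0))
  # short-mode mean: truncated exponential calibrated to bd_short_mean
  cfg <- network_config("WT", seed = 7L, p_long = 0)
  bds <- sample_burst_durations(cfg, 1e4)
  se <- stats::sd(bds) / sqrt(length(bds))
  expect_lt(abs(mean(bds) - 0.75), 3 * se)
  expect_equal(sum(bds > 15), 0) # p_long = 0 never yields long events
  # mutant support gap: nothing between 4 and 16 s
  mb <- sample_burst_durations(network_config("Mutant", seed = 7L), 1e4)
  expect_identical(sum(mb > 4 & mb < 16), 0L)
  expect_true(all(mb > 0 & mb <= 32))
})

test_that("up-state schedules are disjoint, seeded, and degenerate inputs behave", {
  cfg <- network_config("WT", seed = 3L)
  expect_identical(nrow(sample_upstate_schedule(cfg, 0)), 0L)
  expect_warning(s_short <- sample_upstate_schedule(cfg, 5), "shorter")
  s1 <- sample_upstate_schedule(cfg, 1200)
  s2 <- sample_upstate_schedule(cfg, 1200)
  expect_identical(s1, s2) # bit-exact reproducibility
  ends <- s1$start + s1$bd
  expect_true(all(s1$start[-1] - ends[-nrow(s1)] >= cfg$min_down - 1e-9))
  expect_true(all(ends <= 1200))
})

test_that("generated spikes respect refractoriness, silence between bursts, and the target rate", {
  rec <- wt_rec_10min()
  isi <- unlist(lapply(rec$spikes, diff))
  expect_true(all(isi >= 0.0025 - 1e-12)) # exhaustive ISI scan
  # no spikes outside scheduled up-states
  sched <- rec$truth$schedule
  pooled <- sort(unlist(rec$spikes, use.names = FALSE))
  inside <- rep(FALSE, length(pooled))
  for (i in seq_len(nrow(sched))) {
    inside <- inside | (pooled >= sched$start[i] & pooled <= sched$start[i] + sched$bd[i])
  }
  expect_true(all(inside))
  # array-aggregate rate within 10% of the 68 Hz target
  rate <- sum(lengths(rec$spikes)) / rec$duration
  expect_lt(abs(rate - 68) / 68, 0.10)
  # empty schedule -> all-empty spike lists
  empty <- generate_spikes(sample_upstate_schedule(network_config("WT"), 0),
                           network_config("WT"))
  expect_true(all(lengths(empty$spikes) == 0))
})

test_that("spike counts are conserved against the analytic expectation", {
  cfg <- network_config("WT", seed = 21L)
  rec <- simulate_recording(cfg, 2400) # > 100 up-states
  expect_gt(nrow(rec$truth$schedule), 100)
  n_exp <- expected_spike_count(rec)
  n_obs <- sum(lengths(rec$spikes))
  expect_lt(abs(n_obs - n_exp), 3 * sqrt(n_exp))
})

test_that("generation is bit-exactly reproducible for a fixed seed", {
  cfg <- network_config("Mutant", seed = 9L)
  r1 <- simulate_recording(cfg, 300)
  r2 <- simulate_recording(cfg, 300)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$truth$engaged, r2$truth$engaged)
})

test_that("drug effects scale rates and the long mode as a Hill inhibition", {
  cfg <- network_config("WT", seed = 2L)
  # concentration 0 is the identity
  same <- apply_drug(cfg, drug_effect("CBZ", 0))
  expect_equal(same$target_array_rate, cfg$target_array_rate)
  expect_equal(same$p_long, cfg$p_long)
  # Hill midpoint: C = IC50 halves the rate exactly (hill 1)
  half <- apply_drug(cfg, drug_effect("CBZ", 49e-6))
  expect_equal(half$drug$rate_scale, 0.5)
  expect_equal(half$target_array_rate, cfg$target_array_rate / 2)
  expect_error(drug_effect("CBZ", -1e-6), "non-negative")
  # gabazine abolishes the long mode: no schedule bd above the gap upper bound
  gz <- apply_drug(network_config("Mutant", seed = 4L, p_long = 0.05),
                   drug_effect("gabazine", 1e-6))
  expect_equal(gz$p_long, 0)
  bds <- sample_burst_durations(gz, 5000)
  expect_true(all(bds <= gz$gap_range[1]))
})

test_that("array rate declines monotonically along a CBZ series with ~half block at IC50", {
  rates <- vapply(c(0, 49e-6, 2000e-6), function(conc) {
    cfg <- apply_drug(network_config("WT", seed = 31L), drug_effect("CBZ", conc))
    rec <- suppressWarnings(simulate_recording(cfg, 600))
    sum(lengths(rec$spikes)) / rec$duration
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_lt(abs(rates[2] / rates[1] - 0.5), 0.05)
})

test_that("waveform templates are stable within units and across burst types", {
  rec <- wt_rec_10min()
  # noiseless, uncontaminated: all spikes bit-identical to the template
  clean_bank <- generate_waveforms(rec, noise_sd = 0, contam_frac = 0)
  tpl <- attr(clean_bank, "templates")
  u <- names(clean_bank)[1]
  expect_true(all(apply(clean_bank[[u]]$waveforms, 1, function(w)
    isTRUE(all.equal(w, tpl[[u]], tolerance = 1e-12)))))
  # mean waveform inside the longest up-state matches the mean outside it
  bank <- generate_waveforms(rec, seed = 5L)
  sched <- rec$truth$schedule
  long_i <- which.max(sched$bd)
  win <- c(sched$start[long_i], sched$start[long_i] + sched$bd[long_i])
  uu <- names(bank)[which.max(lengths(rec$spikes))]
  wf <- bank[[uu]]$waveforms[!bank[[uu]]$contaminant, , drop = FALSE]
  tms <- bank[[uu]]$spike_times[!bank[[uu]]$contaminant]
  in_l <- tms >= win[1] & tms <= win[2]
  expect_gt(sum(in_l), 3)
  diff_mean <- colMeans(wf[in_l, , drop = FALSE]) - colMeans(wf[!in_l, , drop = FALSE])
  expect_lt(max(abs(diff_mean)), 5 * 0.05 / sqrt(min(sum(in_l), sum(!in_l))))
})
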