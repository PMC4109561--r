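test_that("refractory cleaning matches the sequential-scan oracle", {
  expect_identical(clean_refractory(numeric(0)),
                   list(times = numeric(0), n_removed = 0L))
  # worked example (times in ms): [0, 1.0, 2.0, 2.4, 10] -> keep [0, 10]
  tms <- c(0, 1.0, 2.0, 2.4, 10) / 1000
  out <- clean_refractory(tms)
  expect_equal(out$times, c(0, 0.010))
  expect_identical(out$n_removed, 3L)
  expect_error(clean_refractory(c(0.2, 0.1)), "sorted")
  # property: oracle equivalence, idempotence, order preservation on random trains
  for (s in 1:20) {
    set.seed(s)
    tr <- sort(cumsum(rexp(200, rate = 400)))
    out1 <- clean_refractory(tr)
    expect_equal(out1$times, oracle_refractory(tr))
    expect_true(all(diff(out1$times) >= 0.0025 - 1e-12))
    expect_identical(out1$times[1], tr[1]) # first spike never removed
    out2 <- clean_refractory(out1$times)
    expect_identical(out2$n_removed, 0L) # idempotent
  }
})

test_that("noiseless distinct templates sort perfectly and a duplicated single unit is flagged", {
  t1 <- meaburst:::wave_template(1, 2.2)
  t2 <- meaburst:::wave_template(0.6, 3.0)
  wf <- rbind(matrix(rep(t1, each = 60), 60), matrix(rep(t2, each = 60), 60))
  res <- sort_waveforms(wf, 2)
  expect_identical(sum(res$removed), 0L)
  expect_lt(res$manova_p, 0.01)
  expect_true(res$valid)
  expect_identical(length(unique(res$cluster[1:60])), 1L)
  expect_identical(length(unique(res$cluster[61:120])), 1L)
  expect_false(res$cluster[1] == res$cluster[61])
  # single template duplicated as two expected units: not distinct, flagged
  set.seed(42)
  wf0 <- matrix(rep(t1, each = 300), 300) + matrix(rnorm(300 * 48, 0, 0.05), 300)
  res0 <- sort_waveforms(wf0, 2)
  expect_gte(res0$manova_p, 0.01)
  expect_false(res0$valid)
  # degenerate identical waveforms refuse to cluster
  expect_error(sort_waveforms(matrix(rep(t1, each = 20), 20), 2), "degenerate")
  expect_error(sort_waveforms(wf, 0), "expected_units")
})

test_that("sorting removes most contaminants at threshold 1.4 with <10% total exclusion", {
  rec <- wt_rec_10min()
  bank <- generate_waveforms(rec) # default 5% contamination
  sr <- suppressWarnings(sort_recording(rec, bank, manova_reps = 99L))
  rm_c <- 0; tot_c <- 0; rm_g <- 0; tot_g <- 0
  for (u in names(bank)) {
    ct <- bank[[u]]$contaminant
    rm <- sr$removed_by_unit[[u]]
    rm_c <- rm_c + sum(ct & rm); tot_c <- tot_c + sum(ct)
    rm_g <- rm_g + sum(!ct & rm); tot_g <- tot_g + sum(!ct)
  }
  expect_gt(rm_c / tot_c, 0.5) # audit against generator ground truth
  expect_lt(sr$fraction_removed, 0.10)
  # combined refractory + sorting exclusion stays under the 10% contract
  refrac_removed <- sum(attr(rec, "refractory_removed"))
  total <- sum(lengths(rec$spikes)) + refrac_removed
  expect_lt((refrac_removed + rm_c + rm_g) / total, 0.10)
})

test_that("irregular electrodes are excluded by rate and silence criteria", {
  rec <- wt_rec_10min()
  # all units active -> identity
  kept <- exclude_irregular_electrodes(rec)
  expect_identical(kept$units, rec$units)
  # the WT preset keeps at least 25 active electrodes
  expect_gte(length(unique(kept$units$electrode_id)), 25)
  # a unit silent for most of the recording drags its electrode out
  spikes <- list(u1 = seq(1, 599, by = 0.5), u2 = c(2.0, 2.3))
  toy <- make_recording(spikes, 600, electrode_id = c(1L, 2L))
  out <- exclude_irregular_electrodes(toy, min_rate = 0.05,
                                      max_silent_fraction = 0.5,
                                      segment_len = 60)
  expect_identical(out$units$unit_id, "u1")
  expect_error(exclude_irregular_electrodes(
    make_recording(list(u1 = numeric(0)), 600), min_rate = 0.05), "excluded")
})
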