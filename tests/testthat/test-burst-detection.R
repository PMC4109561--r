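test_that("degenerate inputs and threshold validation behave", {
  silent <- make_recording(list(u1 = numeric(0), u2 = numeric(0)), 60)
  expect_identical(nrow(detect_upstates(silent)), 0L)
  rec <- make_recording(list(u1 = c(1, 2, 3)), 10)
  expect_error(detect_upstates(rec, high_thr = 2, low_thr = -1), "positive")
  expect_error(detect_upstates(rec, high_thr = 2, low_thr = 5), "low_thr")
})

test_that("two dense firing episodes are detected with the right durations", {
  set.seed(5)
  spikes <- lapply(1:3, function(i) {
    sort(c(runif(60, 1.0, 1.5), runif(30, 5.0, 5.2)))
  })
  names(spikes) <- paste0("u", 1:3)
  rec <- make_recording(spikes, 10)
  ups <- detect_upstates(rec, window = 0.01, high_thr = 3, low_thr = 2,
                         min_interburst = 0.5)
  expect_identical(nrow(ups), 2L)
  expect_lt(abs(ups$bd[1] - 0.5), 0.05)
  expect_lt(abs(ups$bd[2] - 0.2), 0.05)
  # matches the exhaustive 1 ms-scan oracle
  orc <- oracle_detect(rec, window = 0.01, high_thr = 3, low_thr = 2,
                       min_interburst = 0.5)
  expect_equal(ups$start, orc$start)
  expect_equal(ups$end, orc$end)
})

test_that("detector matches the 1 ms-scan oracle on short random recordings", {
  for (s in 1:3) {
    cfg <- network_config("WT", seed = 40L + s, n_excitatory = 10L,
                          n_inhibitory = 4L, target_array_rate = 25,
                          ibi_mean = 6)
    rec <- simulate_recording(cfg, 50)
    ups <- detect_upstates(rec, window = 0.01, high_thr = 4, low_thr = 2,
                           min_interburst = 0.1)
    orc <- oracle_detect(rec, window = 0.01, high_thr = 4, low_thr = 2,
                         min_interburst = 0.1)
    expect_equal(ups$start, orc$start, tolerance = 1e-9)
    expect_equal(ups$end, orc$end, tolerance = 1e-9)
  }
})

test_that("a long seizure-like event is detected as one unfragmented up-state", {
  cfg <- network_config("Mutant", seed = 17L, p_long = 0.02)
  rec <- simulate_recording(cfg, 3600)
  sched <- rec$truth$schedule
  expect_gt(sum(sched$bd >= 16), 0)
  ups <- detect_upstates(rec)
  expect_identical(nrow(ups), nrow(sched))
  i_long <- which.max(sched$bd)
  j <- which(ups$start >= sched$start[i_long] - 0.5 &
               ups$start < sched$start[i_long] + sched$bd[i_long])
  expect_identical(length(j), 1L)
  expect_lt(abs(ups$bd[j] - sched$bd[i_long]), 0.2)
})

test_that("pooled SN is conserved and raising the opening threshold is monotone", {
  rec <- wt_rec_10min()
  ups <- wt_ups_10min()
  expect_lte(sum(ups$pooled_sn), sum(lengths(rec$spikes)))
  n_by_thr <- vapply(c(5, 10, 17, 40, 200), function(h)
    nrow(detect_upstates(rec, high_thr = h)), integer(1))
  expect_true(all(diff(n_by_thr) <= 0))
})

test_that("per-unit burst annotations follow the 1- and 2-spike rules", {
  carrier <- lapply(1:3, function(i) sort(runif(120, 1.0, 1.5)))
  names(carrier) <- paste0("c", 1:3)
  spikes <- c(carrier, list(single = 1.2, pair = c(1.10, 1.13),
                            five = c(1.00, 1.01, 1.02, 1.03, 1.04)))
  rec <- make_recording(spikes, 10)
  ups <- detect_upstates(rec, window = 0.01, high_thr = 3, low_thr = 2,
                         min_interburst = 0.2)
  expect_identical(nrow(ups), 1L)
  ann <- annotate_unit_bursts(ups, rec)
  expect_equal(ann$bd_unit[ann$unit_id == "single"], 0.002) # exactly 2 ms
  expect_identical(ann$sn[ann$unit_id == "single"], 1L)
  expect_equal(ann$bd_unit[ann$unit_id == "pair"], 0.03, tolerance = 1e-9)
  expect_identical(ann$sn[ann$unit_id == "pair"], 2L)
  expect_equal(ann$bd_unit[ann$unit_id == "five"], 0.04, tolerance = 1e-9)
  expect_identical(ann$sn[ann$unit_id == "five"], 5L)
  # non-engaged units absent
  expect_false("absent" %in% ann$unit_id)
})

test_that("tonic units are discarded and quiet networks are untouched", {
  rec <- wt_rec_10min()
  ups <- wt_ups_10min()
  out <- discard_tonic_units(rec, ups)
  expect_lte(length(attr(out, "tonic_removed")), 2) # 0-2 per network
  # a planted 5 Hz tonic unit is removed
  rec2 <- rec
  rec2$spikes$tonic <- seq(0.05, rec$duration - 0.05, by = 0.2)
  rec2$units <- rbind(rec2$units,
                      data.frame(unit_id = "tonic", electrode_id = 99L,
                                 true_class = NA_character_))
  out2 <- discard_tonic_units(rec2, ups)
  expect_true("tonic" %in% attr(out2, "tonic_removed"))
  expect_false("tonic" %in% out2$units$unit_id)
})

test_that("auto-tuned thresholds are deterministic and recover the schedule", {
  rec <- wt_rec_10min()
  tuned1 <- auto_tune_thresholds(rec)
  tuned2 <- auto_tune_thresholds(rec)
  expect_identical(tuned1, tuned2)
  ups <- detect_upstates(rec, window = tuned1$window, high_thr = tuned1$high_thr,
                         low_thr = tuned1$low_thr,
                         min_interburst = tuned1$min_interburst)
  sched <- rec$truth$schedule
  hit <- vapply(seq_len(nrow(sched)), function(i)
    any(ups$start < sched$start[i] + sched$bd[i] & ups$end > sched$start[i]),
    logical(1))
  expect_gte(mean(hit), 0.95)
  expect_lte(tuned1$min_interburst, 0.2) # never above the shortest scheduled gap
})
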