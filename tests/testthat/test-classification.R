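test_that("well-separated synthetic populations match the nearest-centroid oracle", {
  set.seed(8)
  n1 <- 40; n2 <- 14
  truth <- rep(c("excitatory", "inhibitory"), c(n1, n2))
  df <- data.frame(
    unit_id = sprintf("u%03d", 1:(n1 + n2)),
    ff = c(rnorm(n1, 3, 0.3), rnorm(n2, 9, 0.3)),       # > 5 SD apart
    bd_mean = c(rnorm(n1, 0.5, 0.05), rnorm(n2, 0.7, 0.05)),
    sn_mean = c(rnorm(n1, 10, 1), rnorm(n2, 30, 1)),
    ibsr = c(rnorm(n1, 20, 1.5), rnorm(n2, 45, 1.5)),
    stringsAsFactors = FALSE)
  cls <- classify_units(df)
  # nearest-centroid brute-force oracle in standardized feature space
  xs <- scale(as.matrix(df[, c("ff", "bd_mean", "sn_mean", "ibsr")]))
  cen <- rbind(colMeans(xs[truth == "excitatory", ]),
               colMeans(xs[truth == "inhibitory", ]))
  oracle <- c("excitatory", "inhibitory")[apply(xs, 1, function(r)
    which.min(colSums((t(cen) - r)^2)))]
  got <- cls$labels[cls$labels != "outlier"]
  expect_identical(unname(got), oracle[match(names(got), df$unit_id)])
  # invariance to feature scaling: standardization absorbs units
  df2 <- df
  df2$ibsr <- df2$ibsr * 1000
  cls2 <- classify_units(df2)
  expect_identical(cls2$labels, cls$labels)
})

test_that("identical unit features refuse to cluster", {
  df <- data.frame(unit_id = sprintf("u%02d", 1:12), ff = 2, bd_mean = 0.5,
                   sn_mean = 10, ibsr = 20)
  expect_error(classify_units(df), "identical|degenerate")
})

test_that("the generator's excitatory/inhibitory split is recovered from firing statistics", {
  rec <- wt_rec_1h()
  cls <- wt_classes_1h()
  tab <- table(factor(cls$labels, levels = c("excitatory", "inhibitory", "outlier")))
  # configured 52/17 recovered up to outliers
  expect_lte(abs(unname(tab["excitatory"]) + unname(tab["outlier"]) - 52), 10)
  truth <- stats::setNames(rec$units$true_class, rec$units$unit_id)
  lab <- cls$labels[cls$labels != "outlier"]
  expect_gte(mean(lab == truth[names(lab)]), 0.90)
  # deterministic for a fixed seed
  expect_identical(classify_units(wt_stats_1h())$labels, cls$labels)
})

test_that("four planted up-state components are recovered and SN rises across states", {
  # four well-separated (BD, SN) components
  set.seed(3)
  n_per <- 15
  bds <- c(0.08, 0.4, 1.2, 3.0)
  rates <- c(450, 650, 900, 1300) # pooled spikes/s within burst
  onset <- 5
  spk <- vector("list", 12)
  starts <- c(); comp <- c()
  for (ci in 1:4) for (r in 1:n_per) {
    bd <- bds[ci] * runif(1, 0.95, 1.05)
    n_spk <- rpois(1, rates[ci] * bd)
    tt <- sort(runif(max(n_spk, 12), onset, onset + bd))
    # every unit engaged in every burst: separation is carried by (BD, SN)
    u_of <- c(sample(1:12), sample(1:12, length(tt) - 12, replace = TRUE))
    for (u in 1:12) spk[[u]] <- c(spk[[u]], tt[u_of == u])
    starts <- c(starts, onset); comp <- c(comp, ci)
    onset <- onset + bd + 3
  }
  names(spk) <- sprintf("u%02d", 1:12)
  rec <- make_recording(spk, onset + 5)
  ups <- detect_upstates(rec, window = 0.02, high_thr = 4, low_thr = 2,
                         min_interburst = 0.5)
  expect_identical(nrow(ups), length(comp))
  sa <- classify_states(rec, ups)
  # optimal label matching over all 24 permutations
  perms <- list(); k <- 0
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4) {
    p <- c(a, b, cc, d)
    if (length(unique(p)) == 4) { k <- k + 1; perms[[k]] <- p }
  }
  acc <- max(vapply(perms, function(p) mean(p[comp] == sa$state), numeric(1)))
  expect_gte(acc, 0.95)
  # all up-states identical -> degenerate error
  ups_same <- ups[rep(1L, 40), , drop = FALSE]
  expect_error(classify_states(rec, ups_same), "distinct")
})

test_that("states of a control culture have nondecreasing SN and the expected engagement", {
  rec <- wt_rec_1h()
  ups <- wt_ups_1h()
  sa <- wt_states_1h()
  expect_true(all(diff(sa$mean_sn) > 0))
  cls <- wt_classes_1h()
  # excitatory engagement rises from ~60% in state 1 toward 1 in state 4
  e1 <- engagement_fraction(rec, ups, sa, cls, "excitatory", 1)
  e4 <- engagement_fraction(rec, ups, sa, cls, "excitatory", 4)
  expect_lt(abs(e1 - 0.60), 0.10)
  expect_gt(e4, 0.95)
  # inhibitory units are always engaged, in every state
  for (s in 1:4) {
    expect_gte(engagement_fraction(rec, ups, sa, cls, "inhibitory", s), 0.999)
  }
  # fully-engaged class trivially gives 1
  expect_error(engagement_fraction(rec, ups, rep(9L, nrow(ups)), cls,
                                   "excitatory", 1), "no up-states")
})
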