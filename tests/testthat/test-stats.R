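test_that("histogram alignment zero-pads the union of bin ranges", {
  h1 <- bd_histogram(c(0.1, 0.6), 10)          # bins up to 0.75
  h2 <- bd_histogram(c(0.1, 1.9), 10)          # bins up to 2.0
  al <- align_histograms(h1, h2)
  expect_identical(length(al$v1), length(al$v2))
  expect_equal(sum(al$v1), 2)
  expect_equal(al$v1[8], 0)                     # padded region
  expect_equal(al$v2[8], 1)                     # 1.9 s burst
  # identical supports: identity
  al2 <- align_histograms(h1, h1)
  expect_equal(al2$v1, al2$v2)
  expect_error(align_histograms(h1, bd_histogram(0.3, 10, bin_width = 0.5)),
               "incompatible")
  # empty vs nonempty: zeros against counts at equal length
  h0 <- bd_histogram(numeric(0), 10)
  al3 <- align_histograms(h0, h2)
  expect_equal(sum(al3$v1), 0)
  expect_identical(length(al3$v1), length(al3$v2))
})

test_that("rank tests reproduce exact and degenerate references", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p.value, 0.1) # exact two-sided: 2/20 orderings
  expect_identical(mw$method, "exact")
  kw0 <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p.value, 1)
  w0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$p.value, 1)
  expect_error(kruskal_wallis(list(1:3)), "list")
})

test_that("exact enumeration agrees with the asymptotic approximation at the boundary sizes", {
  # Mann-Whitney at the exact/approximate boundary (n = 6 + 6): the corrected
  # normal approximation tracks the exact enumeration to within 0.02
  set.seed(2)
  for (r in 1:40) {
    x <- rnorm(6); y <- rnorm(6)
    ex <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    expect_lt(abs(mann_whitney(x, y)$p.value - ex), 1e-12) # we report the exact value
    ap <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(ex - ap), 0.02)
  }
  # Kruskal-Wallis at total n = 10: the chi-square approximation is coarser;
  # the exact enumeration stays within its known ~0.1 envelope of it
  set.seed(3)
  for (r in 1:20) {
    g <- list(rnorm(3), rnorm(3), rnorm(4))
    ex <- kruskal_wallis(g, exact_max = 10L)
    expect_identical(ex$method, "exact enumeration")
    ap <- kruskal_wallis(g, exact_max = 0L)
    expect_lt(abs(ex$p.value - ap$p.value), 0.1)
  }
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(6)
  x <- rexp(15); y <- rexp(18, 0.6)
  f <- function(v) log(v + 1)^3
  expect_equal(mann_whitney(x, y)$p.value, mann_whitney(f(x), f(y))$p.value)
  g <- list(rexp(8), rexp(8, 0.5), rexp(8, 0.25))
  expect_equal(kruskal_wallis(g)$p.value, kruskal_wallis(lapply(g, f))$p.value)
})

test_that("type-I error stays near nominal on null burst-duration samples", {
  cfg <- network_config("WT", seed = 55L)
  pool <- sample_burst_durations(cfg, 60000)
  n_rep <- 2000
  rej <- matrix(FALSE, n_rep, 3)
  set.seed(99)
  for (r in seq_len(n_rep)) {
    x <- pool[sample.int(60000, 15)]
    y <- pool[sample.int(60000, 15)]
    z <- pool[sample.int(60000, 15)]
    rej[r, 1] <- mann_whitney(x, y)$p.value < 0.05
    rej[r, 2] <- wilcoxon_signed_rank(x, y)$p.value < 0.05
    rej[r, 3] <- kruskal_wallis(list(x, y, z))$p.value < 0.05
  }
  expect_true(all(colMeans(rej) <= 0.06))
})

test_that("control and epileptiform duration samples differ overwhelmingly", {
  wt <- sample_burst_durations(network_config("WT", seed = 61L), 800)
  mut <- sample_burst_durations(network_config("Mutant", seed = 62L), 800)
  expect_lt(mann_whitney(wt, mut)$p.value, 1e-4)
  expect_lt(kruskal_wallis(list(wt, mut))$p.value, 1e-4)
})

test_that("Dunn's post hoc isolates shifted groups consistently with a permutation oracle", {
  set.seed(13)
  base <- rnorm(20); g2 <- rnorm(20)
  shifted <- rnorm(20) + 10
  dn <- dunn_posthoc(list(base, g2, shifted))
  expect_identical(dn$partition[1], dn$partition[2])
  expect_false(dn$partition[3] == dn$partition[1])
  # three identical groups: all adjusted p = 1, single component
  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  dn0 <- dunn_posthoc(same)
  expect_true(all(dn0$p.adjusted[upper.tri(dn0$p.adjusted)] == 1))
  expect_identical(length(unique(dn0$partition)), 1L)
  expect_error(dunn_posthoc(list(1:3, 4:6)), "3 groups")
  # permutation oracle on the pairwise rank-mean differences
  groups <- list(base, g2, shifted)
  sizes <- lengths(groups)
  pooled <- unlist(groups)
  grp <- rep(1:3, sizes)
  obs_stat <- function(lab) {
    rk <- rank(pooled)
    rb <- tapply(rk, lab, mean)
    c(abs(rb[1] - rb[2]), abs(rb[1] - rb[3]), abs(rb[2] - rb[3]))
  }
  obs <- obs_stat(grp)
  set.seed(14)
  perm <- replicate(4000, obs_stat(sample(grp)))
  p_perm <- (1 + rowSums(perm >= obs - 1e-12)) / 4001
  sig_perm <- p_perm * 3 < 0.05 # Bonferroni, as in Dunn
  sig_dunn <- c(dn$p.adjusted[1, 2], dn$p.adjusted[1, 3], dn$p.adjusted[2, 3]) < 0.05
  expect_identical(unname(sig_perm), unname(sig_dunn))
})
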