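#' Align two histograms by zero-padding empty bins
#'
#' Histograms from different experiments rarely cover the same duration range;
#' to compare them bin-by-bin the bin number is uniformed by adding zeros in
#' the bins one histogram lacks. Requires the same bin width and a common
#' origin (edges at integer multiples of the width).
#'
#' @param h1,h2 `bd_histogram` objects.
#' @return `list(v1, v2, edges)`: equal-length count vectors over the union of
#'   the two bin ranges.
#' @export
align_histograms <- function(h1, h2) {
  stopifnot(inherits(h1, "bd_histogram"), inherits(h2, "bd_histogram"))
  w1 <- h1$meta$bin_width; w2 <- h2$meta$bin_width
  if (abs(w1 - w2) > 1e-9) stopf("incompatible bin widths (%.4g vs %.4g)", w1, w2)
  off <- function(h) h$bin_edges[1] / w1
  if (abs(off(h1) - round(off(h1))) > 1e-6 || abs(off(h2) - round(off(h2))) > 1e-6)
    stopf("bin origins are not multiples of the bin width")
  lo <- min(h1$bin_edges[1], h2$bin_edges[1])
  hi <- max(max(h1$bin_edges), max(h2$bin_edges))
  nb <- as.integer(round((hi - lo) / w1))
  place <- function(h) {
    v <- numeric(nb)
    i0 <- as.integer(round((h$bin_edges[1] - lo) / w1))
    v[i0 + seq_along(h$counts)] <- h$counts
    v
  }
  list(v1 = place(h1), v2 = place(h2), edges = lo + w1 * (0:nb))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples; exact enumeration
#' for small untied samples (total n <= 12), normal approximation with tie
#' correction otherwise (base R conventions).
#'
#' @param x,y numeric samples.
#' @return `list(statistic, p.value, method)` with the U statistic.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("need at least 2 observations per sample")
  small <- (length(x) + length(y)) <= 12
  ties <- anyDuplicated(c(x, y)) > 0
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = small && !ties,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (small && !ties) "exact" else "normal approximation")
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired comparison (e.g. of per-bin counts of two aligned
#' histograms); exact for small untied pair sets, normal approximation with
#' tie correction otherwise.
#'
#' @param x,y paired numeric samples of equal length (`y` may be omitted if
#'   `x` already holds the paired differences).
#' @return `list(statistic, p.value, method)` with the signed-rank statistic.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stopf("paired samples must have equal length")
    x - y
  }
  if (length(d) < 2) stopf("need at least 2 pairs")
  if (all(d == 0)) return(list(statistic = 0, p.value = 1, method = "degenerate"))
  small <- length(d) <= 12
  ties <- anyDuplicated(abs(d[d != 0])) > 0 || any(d == 0)
  ht <- suppressWarnings(stats::wilcox.test(d, exact = small && !ties, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (small && !ties) "exact" else "normal approximation")
}

# All assignments of n pooled observations to groups of sizes `sizes`:
# recursively choose index subsets. Used by the exact Kruskal-Wallis test.
kw_statistic <- function(ranks, grp, sizes, N) {
  rbar <- tapply(ranks, grp, mean)
  12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
}

kw_tie_correction <- function(values, N) {
  t <- table(values)
  1 - sum(t^3 - t) / (N^3 - N)
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric equivalent of one-way ANOVA over two or more groups. For
#' total sample sizes up to `exact_max` (default 10) the permutation null is
#' enumerated exactly over all assignments of the pooled observations to the
#' group sizes; otherwise the chi-square approximation with midrank tie
#' correction is used (via [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors.
#' @param exact_max largest total n for exact enumeration.
#' @return `list(statistic, p.value, df, method)` with the H statistic.
#' @export
kruskal_wallis <- function(groups, exact_max = 10L) {
  if (!is.list(groups) || length(groups) < 2) stopf("groups must be a list of >= 2 samples")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stopf("need at least 2 observations per group")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  k <- length(groups)
  if (length(unique(pooled)) == 1) {
    return(list(statistic = 0, p.value = 1, df = k - 1, method = "degenerate"))
  }
  if (N <= exact_max) {
    ranks <- rank(pooled)
    grp <- rep(seq_len(k), sizes)
    tie_c <- kw_tie_correction(pooled, N)
    h_obs <- kw_statistic(ranks, grp, sizes, N) / tie_c
    # enumerate all distinct assignments of the pooled positions to groups
    acc <- 0; tot <- 0
    recurse <- function(free, lab, gi) {
      if (gi == k) {
        lab[free] <- k
        h <- kw_statistic(ranks, lab, sizes, N) / tie_c
        tot <<- tot + 1
        if (h >= h_obs - 1e-12) acc <<- acc + 1
        return(invisible(NULL))
      }
      cmb <- utils::combn(free, sizes[gi])
      for (cidx in seq_len(ncol(cmb))) {
        lab2 <- lab
        lab2[cmb[, cidx]] <- gi
        recurse(setdiff(free, cmb[, cidx]), lab2, gi + 1L)
      }
    }
    recurse(seq_len(N), integer(N), 1L)
    return(list(statistic = h_obs, p.value = acc / tot, df = k - 1,
                method = "exact enumeration"))
  }
  g <- factor(rep(seq_len(k), sizes))
  ht <- stats::kruskal.test(pooled, g)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter), method = "chi-square approximation")
}

#' Dunn's post hoc multiple comparison
#'
#' Pairwise z comparisons on the pooled midranks after a Kruskal-Wallis test,
#' with Bonferroni-corrected two-sided p-values, plus a partition of the groups
#' into sets not mutually distinguishable at the corrected level (connected
#' components of the "not significantly different" graph).
#'
#' @param groups list of >= 3 numeric vectors.
#' @param alpha significance level applied to the corrected p-values.
#' @return `list(z, p.adjusted, partition, alpha)`; `partition` is an integer
#'   vector assigning each group to a component.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3)
    stopf("Dunn's test needs >= 3 groups (use mann_whitney for 2)")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stopf("need at least 2 observations per group")
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  ranks <- rank(pooled)
  grp <- rep(seq_len(k), sizes)
  rbar <- tapply(ranks, grp, mean)
  tie <- table(pooled)
  tie_term <- sum(tie^3 - tie) / (12 * (N - 1))
  m <- k * (k - 1) / 2
  z <- matrix(NA_real_, k, k)
  padj <- matrix(NA_real_, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sizes[i] + 1 / sizes[j]))
    zij <- (rbar[i] - rbar[j]) / se
    pij <- min(1, 2 * stats::pnorm(-abs(zij)) * m)
    z[i, j] <- z[j, i] <- zij
    padj[i, j] <- padj[j, i] <- pij
  }
  # union-find over the "not distinguishable" edges
  parent <- seq_len(k)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (padj[i, j] >= alpha) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  partition <- match(roots, unique(roots))
  list(z = z, p.adjusted = padj, partition = partition, alpha = alpha)
}
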