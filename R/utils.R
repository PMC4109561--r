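# Internal utilities: seeded evaluation and deterministic seed derivation.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream seed from a master seed and an integer offset. Kept below
# 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  s <- as.numeric(seed) %% 65521
  as.integer((s * 65537 + as.numeric(offset) * 7919 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic multi-start k-means: `nstarts` seeded single starts, best
# total within-cluster sum of squares wins, ties broken by the lowest start.
kmeans_multistart <- function(x, k, nstarts = 20L, seed = 1L, iter.max = 100L) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < k) {
    stopf("k-means degenerate: %d clusters requested but only %d distinct points",
          k, nrow(unique(x)))
  }
  best <- NULL
  for (s in seq_len(nstarts)) {
    km <- with_seed(derive_seed(seed, 7000L + s), {
      tryCatch(stats::kmeans(x, centers = k, nstart = 1, iter.max = iter.max),
               error = function(e) NULL, warning = function(w) NULL)
    })
    if (is.null(km) || any(km$size == 0)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12) best <- km
  }
  if (is.null(best)) {
    stopf("k-means failed for all %d starts (empty cluster or degenerate data)", nstarts)
  }
  best
}
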