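#' Sample-by-taxon incidence matrix
#'
#' Presence/absence (count > 0) derived from a count table, the input to
#' sample-based accumulation curves. Only specimen columns are used.
#'
#' @param x a [count_table()] or a non-negative matrix (taxa x samples).
#' @return logical matrix, samples in rows, taxa in columns.
#' @export
incidence_matrix <- function(x) {
  m <- if (inherits(x, "count_table"))
    x$counts[, specimen_idx(x), drop = FALSE] else as.matrix(x)
  t(m > 0)
}

#' Exact sample-based taxon accumulation curve
#'
#' Analytic expectation of the number of taxa observed in a random
#' subset of k of the N samples, for k = 1..N:
#' `E[S(k)] = sum_i (1 - choose(N - n_i, k) / choose(N, k))`
#' where `n_i` is the number of samples in which taxon i occurs and a
#' binomial coefficient with too-small top is zero. This is the
#' hypergeometric ("exact") sample-based rarefaction estimator.
#'
#' @param m incidence matrix (samples x taxa), as from
#'   [incidence_matrix()].
#' @return data.frame of class `accumulation_curve`: `k`,
#'   `expected_richness`, `sd` (NA for the exact estimator).
#' @export
accumulation_exact <- function(m) {
  m <- as.matrix(m)
  N <- nrow(m)
  if (N < 1) stop("need at least one sample")
  n_i <- colSums(m > 0)
  n_i <- n_i[n_i > 0]
  k <- seq_len(N)
  er <- vapply(k, function(kk) {
    # P(taxon i unseen in a k-subset) = C(N - n_i, k) / C(N, k)
    p_miss <- ifelse(N - n_i < kk, 0,
                     exp(lchoose(N - n_i, kk) - lchoose(N, kk)))
    sum(1 - p_miss)
  }, numeric(1))
  structure(data.frame(k = k, expected_richness = er, sd = NA_real_),
            class = c("accumulation_curve", "data.frame"),
            mode = "exact")
}

#' Permutation-based taxon accumulation curve
#'
#' Richness accumulated along `n_perm` random orderings of the samples;
#' the curve reports the mean and plain standard deviation across
#' permutations at every subset size. At k = N every ordering contains
#' every sample, so the mean equals the total observed richness exactly.
#'
#' @param m incidence matrix (samples x taxa).
#' @param n_perm number of random orderings (>= 1).
#' @param seed integer seed; identical seeds give identical curves.
#' @return data.frame of class `accumulation_curve`: `k`,
#'   `expected_richness`, `sd`, with attributes `n_permutations` and
#'   `seed`.
#' @export
accumulation_random <- function(m, n_perm = 1000L, seed = 1L) {
  m <- as.matrix(m) > 0
  N <- nrow(m)
  if (N < 1) stop("need at least one sample")
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  rich <- matrix(0L, n_perm, N)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(N)
    seen <- rep(FALSE, ncol(m))
    for (k in seq_len(N)) {
      seen <- seen | m[ord[k], ]
      rich[p, k] <- sum(seen)
    }
  }
  sds <- apply(rich, 2, stats::sd)
  if (n_perm == 1) sds <- rep(0, N)
  structure(data.frame(k = seq_len(N),
                       expected_richness = colMeans(rich),
                       sd = sds),
            class = c("accumulation_curve", "data.frame"),
            mode = "random", n_permutations = n_perm, seed = seed)
}

#' Has an accumulation curve reached its plateau?
#'
#' A curve is considered to have reached the asymptote when the richness
#' gained by the final sample, `E[S(N)] - E[S(N-1)]`, is less than or
#' equal to the tolerance (inclusive boundary).
#'
#' @param curve an accumulation curve data.frame (k, expected_richness).
#' @param tolerance non-negative increment below which the curve counts
#'   as flat.
#' @return list with `plateau` (logical) and `last_increment` (numeric).
#' @export
plateau_check <- function(curve, tolerance = 0) {
  if (nrow(curve) < 2) stop("curve must have at least two points")
  er <- curve$expected_richness
  inc <- er[length(er)] - er[length(er) - 1]
  list(plateau = inc <= tolerance, last_increment = inc)
}
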