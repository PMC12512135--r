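#' Label-shuffle permutation test for the reversal distance
#'
#' Builds the null distribution of rd by reassigning the signature's
#' centered rank-ratio values to uniformly random gene subsets of the
#' profile's measured gene universe (equivalent to shuffling the signature
#' labels over the full gene space), recomputing rd for each permutation.
#' The empirical p-value uses add-one smoothing,
#' \eqn{p = (1 + \#\{rd_{null} \ge rd_{obs}\}) / (n_{perm} + 1)},
#' so p is never exactly 0 and is bounded below by \eqn{1/(n_{perm}+1)}.
#'
#' @param pair An `embedded_pair`.
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @param sidedness `"greater"` (default; extreme = large positive rd, the
#'   direction prioritization uses) or `"two_sided"` (extreme = large |rd|).
#' @param universe Optional named numeric vector of centered rank-ratio
#'   values over the profile's full measured gene set; defaults to the
#'   pair's own `d_full`. Must cover at least as many genes as the support.
#' @param return_null If `TRUE`, attach the null rd draws as attribute
#'   `"null_rd"` (used for pooled experiment-wise p-values).
#' @return The permutation p-value (length-1 numeric).
#' @export
permutation_test <- function(pair, n_perm = 1000, seed = NULL,
                             sidedness = c("greater", "two_sided"),
                             universe = NULL, return_null = FALSE) {
  sidedness <- match.arg(sidedness)
  if (!inherits(pair, "embedded_pair")) {
    abort_invalid("`pair` must be an embedded_pair.")
  }
  if (n_perm < 100) {
    abort_invalid("`n_perm` must be at least 100.")
  }
  universe <- universe %||% pair$d_full
  m <- length(pair$support)
  if (length(universe) < m) {
    abort_invalid(sprintf(
      "permutation universe (%d genes) smaller than the signature support (%d).",
      length(universe), m
    ))
  }
  obs <- reversal_distance(pair)
  null_rd <- with_seed(seed, null_rd_draws(pair$g, universe, n_perm))
  p <- perm_pvalue(obs, null_rd, sidedness)
  if (return_null) {
    attr(p, "null_rd") <- null_rd
  }
  p
}

# Vectorized null rd draws: each permutation pairs the signature's centered
# values g with the profile's centered rank values at a random gene subset.
# rd_null = -(g . d_sub) / ||d_sub|| (||g|| is unchanged by relabelling).
null_rd_draws <- function(g, universe, n_perm) {
  m <- length(g)
  n <- length(universe)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n, m), integer(m))
  dmat <- matrix(universe[idx], nrow = m, ncol = n_perm)
  dots <- drop(crossprod(dmat, g))
  norms <- sqrt(colSums(dmat^2))
  norms[norms == 0] <- .Machine$double.eps
  -dots / norms
}

perm_pvalue <- function(obs, null_rd, sidedness = "greater") {
  hits <- if (sidedness == "greater") {
    sum(null_rd >= obs)
  } else {
    sum(abs(null_rd) >= abs(obs))
  }
  unname((1 + hits) / (length(null_rd) + 1))
}

#' Experiment-wise p-value against a pooled null
#'
#' Recomputes each observed rd's p-value against the null rd draws pooled
#' across all profiles tested for the same signature. Pooling raises the
#' attainable resolution from \eqn{1/(n_{perm}+1)} per profile to
#' \eqn{1/(K\,n_{perm}+1)}, which a Bonferroni correction over many drugs
#' requires.
#'
#' @param obs Numeric vector of observed reversal distances.
#' @param pooled_null Numeric vector of pooled null rd draws.
#' @param sidedness `"greater"` or `"two_sided"`.
#' @return Numeric vector of p-values, same length as `obs`.
#' @export
pooled_null_p <- function(obs, pooled_null, sidedness = c("greater", "two_sided")) {
  sidedness <- match.arg(sidedness)
  n <- length(pooled_null)
  if (n == 0) {
    abort_invalid("`pooled_null` is empty.")
  }
  if (sidedness == "greater") {
    sorted <- sort(pooled_null)
    hits <- n - findInterval(obs, sorted, left.open = TRUE)
  } else {
    sorted <- sort(abs(pooled_null))
    hits <- n - findInterval(abs(obs), sorted, left.open = TRUE)
  }
  (1 + hits) / (n + 1)
}
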