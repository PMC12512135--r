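#' Cosine similarity of an embedded pair
#'
#' \eqn{\omega = (g \cdot d) / (\lVert g\rVert \lVert d\rVert)}, the cosine
#' of the angle between the centered rank-ratio vectors. \eqn{\omega = -1}
#' means exactly opposite orientation (the drug profile points against the
#' disease signature), \eqn{+1} parallel orientation.
#'
#' @param x An `embedded_pair`, or a numeric vector (with `y` supplied).
#' @param y Optional second numeric vector when `x` is a vector.
#' @return A single number in \[-1, 1\].
#' @export
cosine_similarity <- function(x, y = NULL) {
  if (inherits(x, "embedded_pair")) {
    g <- x$g
    d <- x$d
  } else {
    if (is.null(y)) {
      abort_invalid("supply an embedded_pair, or two numeric vectors.")
    }
    if (length(x) != length(y)) {
      abort_invalid("`x` and `y` must have equal length.")
    }
    g <- x
    d <- y
  }
  gn <- l2norm(g)
  dn <- l2norm(d)
  if (gn == 0 || dn == 0) {
    abort_degenerate("cosine similarity undefined for a zero-norm vector.")
  }
  unname(clamp_unit(sum(g * d) / (gn * dn), what = "cosine"))
}

#' Reversal distance
#'
#' \eqn{rd = \lVert g\rVert \cos(\pi - \theta) = -\lVert g\rVert\,\omega}:
#' the projection of the disease signature onto the reversed drug-profile
#' direction. Positive rd means the profile points against the signature
#' (candidate therapeutic reversal); negative rd means it mimics the disease.
#' rd ranges over \eqn{[-\lVert g\rVert, +\lVert g\rVert]}, is invariant to
#' positive rescaling of the drug vector, and scales linearly with
#' \eqn{\lVert g\rVert}.
#'
#' @inheritParams cosine_similarity
#' @return A single number.
#' @export
reversal_distance <- function(x, y = NULL) {
  if (inherits(x, "embedded_pair")) {
    gn <- x$g_norm
  } else {
    gn <- l2norm(x)
  }
  -gn * cosine_similarity(x, y)
}

#' Normalized reversal distance
#'
#' Maps the reversal distance onto \eqn{[0, 2]} via
#' \eqn{d = (2/\pi)\,\arccos(rd / \lVert g\rVert)}: 0 for a perfect reverser
#' (antiparallel profile), 1 for an orthogonal profile, 2 for a profile
#' parallel to the disease signature. On vector arguments this quantity is
#' symmetric and satisfies the triangle inequality. Note it is 0 for any
#' exact reverser, not only for identical vectors, so the coincidence axiom
#' of a strict metric does not hold.
#'
#' @param rd Reversal distance (or an `embedded_pair`, in which case
#'   `g_norm` is taken from it).
#' @param g_norm Euclidean norm of the embedded signature vector.
#' @param tol Tolerance for clamping `rd / g_norm` into \[-1, 1\]
#'   (default 1e-12); larger excursions raise a domain error.
#' @return A number in \[0, 2\].
#' @export
normalized_distance <- function(rd, g_norm = NULL, tol = 1e-12) {
  if (inherits(rd, "embedded_pair")) {
    pair <- rd
    g_norm <- pair$g_norm
    rd <- reversal_distance(pair)
  }
  if (is.null(g_norm) || g_norm <= 0) {
    abort_invalid("`g_norm` must be a positive number.")
  }
  ratio <- clamp_unit(rd / g_norm, tol = tol, what = "rd/g_norm")
  (2 / pi) * acos(ratio)
}

#' Sensitivity of the cosine similarity to single-gene perturbations
#'
#' Closed-form partial derivatives of \eqn{\omega} with respect to the i-th
#' element of the drug vector and of the signature vector:
#' \deqn{\partial\omega/\partial d_i = g_i/(\lVert g\rVert\lVert d\rVert) -
#'       d_i (g\cdot d)/(\lVert g\rVert\lVert d\rVert^3)}
#' and symmetrically for \eqn{g_i} (with \eqn{\lVert g\rVert^3} in the
#' second denominator).
#'
#' @param pair An `embedded_pair`.
#' @param genes Gene identifiers in the pair's support (default: all).
#' @return A tibble with columns `gene`, `domega_dd`, `domega_dg`.
#' @export
sensitivity <- function(pair, genes = NULL) {
  if (!inherits(pair, "embedded_pair")) {
    abort_invalid("`pair` must be an embedded_pair.")
  }
  genes <- genes %||% pair$support
  missing <- setdiff(genes, pair$support)
  if (length(missing)) {
    abort(sprintf("gene(s) not in the pair's support: %s",
                  paste(head(missing, 5L), collapse = ", ")),
          class = "tred_error_key")
  }
  g <- pair$g[genes]
  d <- pair$d[genes]
  gn <- pair$g_norm
  dn <- pair$d_norm
  s <- sum(pair$g * pair$d)
  tibble(
    gene = genes,
    domega_dd = unname(g / (gn * dn) - d * s / (gn * dn^3)),
    domega_dg = unname(d / (gn * dn) - g * s / (dn * gn^3))
  )
}

#' Delta-method moments of the cosine similarity
#'
#' First-order delta-method approximation for the mean and variance of
#' \eqn{\omega = h(s, t, u)} with \eqn{s = g\cdot d}, \eqn{t = g\cdot g},
#' \eqn{u = d\cdot d} and \eqn{h(s, t, u) = s/\sqrt{t\,u}}:
#' \deqn{E[h(\Gamma)] \approx h(\gamma), \quad
#'       Var(h(\Gamma)) \approx \nabla h(\gamma)^T \mathrm{Cov}(\Gamma)
#'       \nabla h(\gamma).}
#'
#' @param gamma Length-3 numeric: the mean of \eqn{(s, t, u)}; `t` and `u`
#'   must be positive.
#' @param cov 3x3 symmetric positive-semidefinite covariance of
#'   \eqn{(s, t, u)}.
#' @return An object of class `delta_moments` with fields `mean_approx`,
#'   `var_approx` and `gradient` (the 3-vector \eqn{\nabla h(\gamma)}).
#' @export
delta_moments <- function(gamma, cov) {
  if (!is.numeric(gamma) || length(gamma) != 3L || !all(is.finite(gamma))) {
    abort_invalid("`gamma` must be a finite numeric 3-vector (s, t, u).")
  }
  if (gamma[2] <= 0 || gamma[3] <= 0) {
    abort_invalid("the t and u components of `gamma` must be positive.")
  }
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(3L, 3L)) || !all(is.finite(cov))) {
    abort_invalid("`cov` must be a finite 3x3 matrix.")
  }
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    abort_invalid("`cov` must be symmetric.")
  }
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    abort_invalid("`cov` must be positive semidefinite.")
  }
  s <- gamma[1]; tt <- gamma[2]; u <- gamma[3]
  grad <- c(
    1 / sqrt(tt * u),
    -s / (2 * tt^1.5 * sqrt(u)),
    -s / (2 * u^1.5 * sqrt(tt))
  )
  structure(
    list(
      mean_approx = s / sqrt(tt * u),
      var_approx = max(0, drop(t(grad) %*% cov %*% grad)),
      gradient = grad
    ),
    class = "delta_moments"
  )
}

#' @export
print.delta_moments <- function(x, ...) {
  cat(sprintf("<delta_moments> mean ~ %.6g, var ~ %.6g\n",
              x$mean_approx, x$var_approx))
  invisible(x)
}

#' @export
tidy.delta_moments <- function(x, ...) {
  tibble(term = c("s", "t", "u"), gradient = x$gradient)
}

#' @export
glance.delta_moments <- function(x, ...) {
  tibble(mean_approx = x$mean_approx, var_approx = x$var_approx)
}

#' Softmax prioritization of reversal distances
#'
#' Converts the K reversal distances for one signature into the drug
#' probability distribution \eqn{p_i = \exp(rd_i) / \sum_j \exp(rd_j)},
#' computed with max-subtraction so that large rd values do not overflow.
#'
#' @param rds Numeric vector of reversal distances (names preserved).
#' @return Probabilities summing to 1, in the order of `rds`.
#' @export
softmax_prioritize <- function(rds) {
  if (length(rds) < 1L || !is.numeric(rds) || !all(is.finite(rds))) {
    abort_invalid("`rds` must be a non-empty finite numeric vector.")
  }
  z <- exp(rds - max(rds))
  z / sum(z)
}

#' Drug maximizing the reversal distance
#'
#' Returns the identifier with the largest rd; ties are broken by
#' lexicographically smallest identifier so the selection is deterministic.
#'
#' @param rds Named numeric vector: profile (or drug) id -> rd.
#' @return A single identifier.
#' @export
argmax_drug <- function(rds) {
  if (length(rds) < 1L || !is.numeric(rds) || !all(is.finite(rds))) {
    abort_invalid("`rds` must be a non-empty finite numeric vector.")
  }
  if (is.null(names(rds)) || any(names(rds) == "")) {
    abort_invalid("`rds` must be named by profile identifier.")
  }
  at_max <- names(rds)[rds == max(rds)]
  sort(at_max)[1L]
}
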