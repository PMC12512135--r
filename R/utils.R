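# Internal helpers: error conditions, seeded evaluation, small checks.

abort_invalid <- function(msg, ...) {
  abort(msg, class = "tred_error_invalid_input", ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = "tred_error_format", ...)
}

abort_overlap <- function(msg, ...) {
  abort(msg, class = "tred_error_overlap", ...)
}

abort_degenerate <- function(msg, ...) {
  abort(msg, class = "tred_error_degenerate", ...)
}

abort_domain <- function(msg, ...) {
  abort(msg, class = "tred_error_domain", ...)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_invalid("`seed` must be a single finite number or NULL.")
  }
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

# Derive a reproducible child seed below 2^31 from a parent seed and index.
child_seed <- function(seed, i) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483629
}

check_named_scores <- function(scores, what = "scores") {
  if (!is.numeric(scores) || length(scores) < 2L) {
    abort_invalid(sprintf("`%s` must be a numeric vector with at least 2 genes.", what))
  }
  nm <- names(scores)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    abort_invalid(sprintf("`%s` must be named by gene identifier.", what))
  }
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    abort_invalid(sprintf(
      "duplicate gene identifiers in `%s`: %s", what,
      paste(head(dup, 5L), collapse = ", ")
    ))
  }
  if (!all(is.finite(scores))) {
    abort_invalid(sprintf("all values in `%s` must be finite.", what))
  }
  invisible(scores)
}

l2norm <- function(x) sqrt(sum(x^2))

new_tred_tbl <- function(x, subclass) {
  class(x) <- c(subclass, class(tibble()))
  x
}

# clamp to [-1, 1], erroring if the excursion exceeds `tol`
clamp_unit <- function(x, tol = 1e-12, what = "value") {
  bad <- abs(x) > 1 + tol
  if (any(bad, na.rm = TRUE)) {
    abort_domain(sprintf("%s outside [-1, 1] beyond tolerance (max |%s| = %.15g).",
                         what, what, max(abs(x), na.rm = TRUE)))
  }
  pmin(1, pmax(-1, x))
}
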