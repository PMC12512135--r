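#' @export
tidy.tred_results <- function(x, ...) {
  out <- x
  attr(out, "null_rd") <- NULL
  attr(out, "config") <- NULL
  class(out) <- class(tibble())
  out
}

#' Summarise a results table in one row
#'
#' @param x A `tred_results` tibble.
#' @param ... Unused.
#' @return One-row tibble: pair counts, significance counts, rd range.
#' @export
glance.tred_results <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_signatures = dplyr::n_distinct(x$signature_id),
    n_profiles = dplyr::n_distinct(x$profile_id),
    n_compounds = if ("compound" %in% names(x)) {
      dplyr::n_distinct(x$compound)
    } else NA_integer_,
    max_rd = max(x$rd),
    n_nominal = if ("nominal_sig" %in% names(x)) sum(x$nominal_sig) else NA_integer_,
    n_adj_significant = if ("p_adj" %in% names(x)) {
      sum(x$p_adj < 0.05)
    } else NA_integer_
  )
}

#' @export
tidy.tred_prioritization <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' @export
glance.tred_prioritization <- function(x, ...) {
  tibble(
    n_drugs = nrow(x),
    n_prioritized = sum(x$passes_threshold),
    max_signatures_significant = max(x$n_signatures_significant)
  )
}
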