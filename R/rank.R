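#' Centered rank-ratio transform
#'
#' Converts per-gene scores into rank ratios: each gene's rank divided by the
#' total number of genes ranked, with the largest score receiving rank 1.
#' Under this orientation upregulated genes occupy low rank ratios
#' (uncentered ratio < 0.5). Subtracting 0.5 (the default) centers the ratios
#' on \[-0.5, 0.5\] so that cosine similarity between two transformed vectors
#' spans \[-1, 1\] rather than \[0, 1\].
#'
#' @param scores Named numeric vector of per-gene scores (TWAS Z, logFC, or
#'   any differential-expression statistic). Names are gene identifiers and
#'   must be unique; values must be finite; at least 2 genes.
#' @param ties Tie method passed to [base::rank()] (default `"average"`,
#'   which keeps the mean centered ratio at 0 for a full vector).
#' @param center If `TRUE` (default) subtract 0.5 from each rank ratio.
#'
#' @return Named numeric vector of rank ratios in the order of `scores`,
#'   with attribute `n_total` recording the number of genes ranked.
#'
#' @examples
#' rank_ratio(c(a = 3.2, b = -1.1, c = 0))
#' rank_ratio(c(a = 1, b = 1))   # average ties: both (1+2)/2/2 - 0.5 = 0.25
#' @export
rank_ratio <- function(scores, ties = c("average", "min", "max", "first"),
                       center = TRUE) {
  ties <- match.arg(ties)
  check_named_scores(scores)
  n <- length(scores)
  r <- rank(-scores, ties.method = ties)
  out <- r / n
  if (center) {
    out <- out - 0.5
  }
  names(out) <- names(scores)
  attr(out, "n_total") <- n
  out
}
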