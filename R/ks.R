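#' KS-type enrichment of a tag set in a ranked list
#'
#' Classic connectivity-map enrichment statistic. For t tagged genes at
#' sorted positions pos(1) < ... < pos(t) in a ranked list of n genes,
#' \deqn{a = \max_j (j/t - pos(j)/n), \quad
#'       b = \max_j (pos(j)/n - (j-1)/t),}
#' returning `a` when `a >= b` and `-b` otherwise. Positive values indicate
#' enrichment of the tags toward the top of the list, negative toward the
#' bottom; the statistic lies in \[-1, 1\].
#'
#' @param positions Integer positions (1-based) of the tagged genes in the
#'   ranked list; must be distinct and within `[1, n]`.
#' @param n Length of the ranked list.
#' @return A number in \[-1, 1\].
#' @export
ks_enrichment <- function(positions, n) {
  if (length(positions) < 1L) {
    abort_invalid("the tag set must contain at least one gene.")
  }
  positions <- sort(as.numeric(positions))
  t <- length(positions)
  if (anyDuplicated(positions) || positions[1] < 1 || positions[t] > n) {
    abort_invalid("`positions` must be distinct integers in [1, n].")
  }
  j <- seq_len(t)
  a <- max(j / t - positions / n)
  b <- max(positions / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' KS connectivity score of a signature against a drug profile
#'
#' The baseline pattern-matching score. The disease signature is split at
#' rank ratio 0.5 into disease-upregulated (rank ratio < 0.5) and
#' disease-downregulated (>= 0.5) gene sets. Tag positions are taken in
#' the drug's gene list ordered with the most drug-downregulated gene
#' first, so that a drug which downregulates the disease-up genes and
#' upregulates the disease-down genes (a reverser) scores positively.
#' With both sets present the score is `ks_up - ks_down`, set to 0 when
#' `ks_up` and `ks_down` share their sign; with only an up (down) set it
#' is `ks_up` (`-ks_down`). The score lies in \[-2, 2\]; positive scores
#' indicate potential reversal, negative possible exacerbation.
#'
#' @param sig A `disease_signature` or named numeric vector of raw
#'   signature scores.
#' @param prof Named numeric vector of raw drug profile scores over all
#'   measured genes, or a `profile_matrix` with `profile_id`.
#' @param profile_id Column to use when `prof` is a `profile_matrix`.
#' @param ties Tie method for ranking.
#' @return A list with `score`, `ks_up`, `ks_down`, `n_up`, `n_down`
#'   (counts of signature tags found in the profile).
#' @export
connectivity_score <- function(sig, prof, profile_id = NULL, ties = "average") {
  if (inherits(sig, "disease_signature")) {
    sig <- sig$scores
  }
  if (inherits(prof, "profile_matrix")) {
    if (is.null(profile_id)) {
      abort_invalid("supply `profile_id` when `prof` is a profile_matrix.")
    }
    prof <- profile_scores(prof, profile_id)
  }
  check_named_scores(sig, "signature scores")
  check_named_scores(prof, "profile scores")

  sig_ratio <- rank_ratio(sig, ties = ties, center = FALSE)
  up_genes <- names(sig_ratio)[sig_ratio < 0.5]
  down_genes <- names(sig_ratio)[sig_ratio >= 0.5]

  # drug list ordered most-downregulated-by-drug first
  drug_ratio <- rank_ratio(prof, ties = "first", center = FALSE)
  ord <- names(prof)[order(drug_ratio, decreasing = TRUE)]
  pos_of <- function(genes) which(ord %in% genes)

  up_pos <- pos_of(up_genes)
  down_pos <- pos_of(down_genes)
  n <- length(ord)
  if (length(up_pos) == 0L && length(down_pos) == 0L) {
    abort_invalid("no signature gene is measured in the profile.")
  }
  ks_up <- if (length(up_pos)) ks_enrichment(up_pos, n) else NA_real_
  ks_down <- if (length(down_pos)) ks_enrichment(down_pos, n) else NA_real_
  score <- if (length(up_pos) && length(down_pos)) {
    if (ks_up * ks_down > 0) 0 else ks_up - ks_down
  } else if (length(up_pos)) {
    ks_up
  } else {
    -ks_down
  }
  list(score = score, ks_up = ks_up, ks_down = ks_down,
       n_up = length(up_pos), n_down = length(down_pos))
}
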