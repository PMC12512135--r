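#' Two-standard-deviation flag for a reversal distance
#'
#' A profile's rd is "large" for a signature when it exceeds the mean rd
#' across all drug response profiles tested for that signature by more than
#' two sample standard deviations.
#'
#' @param rd Reversal distance(s) to flag.
#' @param all_rds All reversal distances for the signature (at least 2).
#' @return Logical vector: `rd > mean(all_rds) + 2 * sd(all_rds)`.
#' @export
two_sd_flag <- function(rd, all_rds) {
  if (length(all_rds) < 2L) {
    abort_invalid("`all_rds` needs at least 2 profiles to define the 2-SD rule.")
  }
  if (!all(is.finite(all_rds)) || !all(is.finite(rd))) {
    abort_invalid("reversal distances must be finite.")
  }
  rd > mean(all_rds) + 2 * sd(all_rds)
}

#' Experiment-wise p-value adjustment across drugs
#'
#' Per signature, each profile's experiment-wise p-value is recomputed
#' against the null rd distribution pooled over all profiles tested for
#' that signature (when pooled null draws are available), then Bonferroni
#' corrected with m = number of distinct drugs tested for the signature:
#' `p_adj = min(1, p * m)`.
#'
#' @param results Results tibble with columns `signature_id`, `compound`,
#'   `rd`, `p_perm` (as produced by [tred_permute()]).
#' @param null_rds Optional named list: signature_id -> pooled null rd
#'   draws. When absent, Bonferroni is applied to `p_perm` directly.
#' @param sidedness `"greater"` or `"two_sided"`.
#' @return `results` with a `p_adj` column (and `p_pooled` when pooling).
#' @export
adjust_pvalues <- function(results, null_rds = NULL,
                           sidedness = c("greater", "two_sided")) {
  sidedness <- match.arg(sidedness)
  need <- c("signature_id", "compound", "rd", "p_perm")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    abort_invalid(sprintf("`results` is missing column(s): %s",
                          paste(miss, collapse = ", ")))
  }
  results <- results |>
    dplyr::group_by(.data$signature_id) |>
    dplyr::mutate(.m_drugs = dplyr::n_distinct(.data$compound)) |>
    dplyr::ungroup()
  if (is.null(null_rds)) {
    results$p_adj <- pmin(1, results$p_perm * results$.m_drugs)
  } else {
    results$p_pooled <- NA_real_
    for (sig in unique(results$signature_id)) {
      idx <- results$signature_id == sig
      pool <- null_rds[[sig]]
      if (is.null(pool)) {
        results$p_pooled[idx] <- results$p_perm[idx]
      } else {
        results$p_pooled[idx] <- pooled_null_p(results$rd[idx], pool, sidedness)
      }
    }
    results$p_adj <- pmin(1, results$p_pooled * results$.m_drugs)
  }
  results$.m_drugs <- NULL
  results
}

#' Flag replicate-direction consistency
#'
#' Profiles sharing a replicate group (compound x cell line x dose x time)
#' must agree on the sign of rd: groups of two or more members with mixed
#' signs are marked inconsistent; groups with a single member are flagged
#' `unreplicated`.
#'
#' @param results Results tibble with columns `signature_id`,
#'   `replicate_group`, `rd`.
#' @return `results` with logical columns `replicate_consistent` and
#'   `unreplicated`. Consistency is assessed within each signature.
#' @export
flag_replicates <- function(results) {
  need <- c("signature_id", "replicate_group", "rd")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    abort_invalid(sprintf("`results` is missing column(s): %s",
                          paste(miss, collapse = ", ")))
  }
  results |>
    dplyr::group_by(.data$signature_id, .data$replicate_group) |>
    dplyr::mutate(
      unreplicated = dplyr::n() == 1L,
      replicate_consistent = dplyr::n() == 1L |
        all(sign(.data$rd) == sign(.data$rd[1]))
    ) |>
    dplyr::ungroup()
}

#' Remove replicate-inconsistent profiles
#'
#' Drops every member of replicate groups whose repeated experiments
#' disagree on the direction of rd. Unreplicated profiles pass through
#' (flagged) and should be vetted with [confirmatory_check()].
#'
#' @inheritParams flag_replicates
#' @return Filtered results tibble with the flag columns of
#'   [flag_replicates()].
#' @export
filter_replicates <- function(results) {
  flag_replicates(results) |>
    dplyr::filter(.data$replicate_consistent)
}

#' Confirmatory cell line check for unreplicated profiles
#'
#' An unreplicated profile is supported when the same compound shows a
#' nominally significant rd of the same sign in a different cell line for
#' the same signature.
#'
#' @param results Results tibble with columns `signature_id`, `compound`,
#'   `cell_line`, `rd`, `nominal_sig`, and the flags of
#'   [flag_replicates()].
#' @return `results` with a logical `confirmed` column (`TRUE` for
#'   replicated rows, which need no confirmation; for unreplicated rows,
#'   the confirmatory-cell-line verdict).
#' @export
confirmatory_check <- function(results) {
  need <- c("signature_id", "compound", "cell_line", "rd", "nominal_sig",
            "unreplicated")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    abort_invalid(sprintf("`results` is missing column(s): %s",
                          paste(miss, collapse = ", ")))
  }
  confirmed <- logical(nrow(results))
  for (i in seq_len(nrow(results))) {
    if (!results$unreplicated[i]) {
      confirmed[i] <- TRUE
      next
    }
    others <- results$signature_id == results$signature_id[i] &
      results$compound == results$compound[i] &
      results$cell_line != results$cell_line[i] &
      results$nominal_sig &
      sign(results$rd) == sign(results$rd[i])
    confirmed[i] <- any(others)
  }
  results$confirmed <- confirmed
  results
}

#' Prioritize drugs across disease signatures
#'
#' Rolls profile-level results up to drugs and applies the multi-signature
#' decision rule: a drug passes when (a) at least one of its profiles is
#' significant after adjustment (`p_adj < alpha_adj`), and (b) it supports
#' at least `min_signatures` signatures, where a signature is "supported"
#' by a profile that is nominally significant, beyond the 2-SD rule,
#' replicate-consistent, and — if unreplicated — confirmed in another cell
#' line. With `require_twas_and_dge = TRUE` the supported signatures must
#' include at least one TWAS and one DGE signature.
#'
#' @param results Results tibble from [tred_permute()] (columns
#'   `signature_id`, `source_kind`, `profile_id`, `compound`, `rd`,
#'   `p_perm`, `p_adj`, `nominal_sig`, `two_sd`, `replicate_consistent`,
#'   `unreplicated`, `confirmed`).
#' @param min_signatures Minimum number of supported signatures (default 1).
#' @param require_twas_and_dge Enforce the TWAS + DGE mix (default FALSE).
#' @param alpha_adj Threshold on the adjusted p-value (default 0.05).
#' @return A `tred_prioritization` tibble, one row per compound, sorted by
#'   descending `n_signatures_significant` then best rd, with
#'   `passes_threshold` marking prioritized drugs.
#' @export
prioritize_drugs <- function(results, min_signatures = 1L,
                             require_twas_and_dge = FALSE, alpha_adj = 0.05) {
  need <- c("signature_id", "profile_id", "compound", "rd", "p_adj",
            "nominal_sig", "two_sd", "replicate_consistent", "unreplicated",
            "confirmed")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    abort_invalid(sprintf("`results` is missing column(s): %s",
                          paste(miss, collapse = ", ")))
  }
  if (!"source_kind" %in% names(results)) {
    results$source_kind <- NA_character_
  }
  res <- results |>
    dplyr::mutate(
      supports = .data$nominal_sig & .data$two_sd &
        .data$replicate_consistent & (!.data$unreplicated | .data$confirmed)
    )
  sig_level <- res |>
    dplyr::group_by(.data$compound, .data$signature_id, .data$source_kind) |>
    dplyr::summarise(sig_supported = any(.data$supports), .groups = "drop")
  out <- res |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      best_signature_id = .data$signature_id[which.max(.data$rd)],
      best_rd = max(.data$rd),
      best_p_adj = min(.data$p_adj),
      has_adj_significant = any(.data$p_adj < alpha_adj),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      sig_level |>
        dplyr::group_by(.data$compound) |>
        dplyr::summarise(
          n_signatures_significant = sum(.data$sig_supported),
          n_twas = sum(.data$sig_supported &
                         .data$source_kind %in% "TWAS"),
          n_dge = sum(.data$sig_supported &
                        .data$source_kind %in% "DGE"),
          .groups = "drop"
        ),
      by = "compound"
    ) |>
    dplyr::mutate(
      passes_threshold = .data$has_adj_significant &
        .data$n_signatures_significant >= min_signatures &
        (!require_twas_and_dge | (.data$n_twas >= 1L & .data$n_dge >= 1L))
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_signatures_significant),
                   dplyr::desc(.data$best_rd))
  new_tred_tbl(out, "tred_prioritization")
}
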