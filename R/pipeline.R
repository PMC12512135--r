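#' Score every signature / profile pair
#'
#' Embeds each disease signature with each drug response profile (centered
#' rank ratios on the shared gene support; drug ranks computed over the
#' profile's full measured gene set first) and computes the closed-form
#' quantities: cosine similarity omega, reversal distance rd, and the
#' normalized distance d_norm in \[0, 2\].
#'
#' @param signatures A `disease_signature`, list of them, or a long tibble
#'   with columns `signature_id`, `source_kind`, `gene`, `score`.
#' @param profiles A [profile_matrix()] (or bare numeric matrix with gene
#'   rownames and profile colnames).
#' @param min_overlap Minimum shared genes per signature (default 10).
#' @param ties Tie method for ranking.
#' @return A `tred_results` tibble with one row per (signature, profile):
#'   ids, perturbation metadata, `n_support`, `n_dropped`, `g_norm`,
#'   `omega`, `rd`, `d_norm`.
#' @examples
#' sim <- simulate_dataset(n_genes = 300, n_drugs = 10, k_signature_genes = 40,
#'                         seed = 1)
#' tred_score(sim$signatures, sim$profiles)
#' @export
tred_score <- function(signatures, profiles, min_overlap = 10,
                       ties = "average") {
  sig_tbl <- as_signature_tbl(signatures)
  profiles <- as_profile_matrix(profiles)
  kinds <- signature_kinds(sig_tbl)
  scores_list <- signature_scores_list(sig_tbl)
  rank_mat <- rank_transform_profiles(profiles, ties = ties)
  meta <- profiles$col_meta

  rows <- lapply(names(scores_list), function(sig_id) {
    sig_scores <- scores_list[[sig_id]]
    check_named_scores(sig_scores, sprintf("signature `%s`", sig_id))
    g_full <- rank_ratio(sig_scores, ties = ties)
    support <- names(g_full)[names(g_full) %in% rownames(rank_mat)]
    if (length(support) < min_overlap) {
      abort_overlap(sprintf(
        "only %d genes shared between signature `%s` and the profile matrix (min_overlap = %d).",
        length(support), sig_id, min_overlap
      ))
    }
    g <- g_full[support]
    gn <- l2norm(g)
    d_sub <- rank_mat[support, , drop = FALSE]
    dnorms <- sqrt(colSums(d_sub^2))
    if (any(dnorms == 0) || gn == 0) {
      abort_degenerate(sprintf(
        "zero-norm embedded vector for signature `%s`.", sig_id))
    }
    omega <- clamp_unit(drop(crossprod(d_sub, g)) / (gn * dnorms),
                        what = "cosine")
    rd <- -gn * omega
    tibble(
      signature_id = sig_id,
      source_kind = unname(kinds[sig_id]),
      profile_id = colnames(rank_mat),
      n_support = length(support),
      n_dropped = length(g_full) - length(support),
      g_norm = gn,
      omega = unname(omega),
      rd = unname(rd),
      d_norm = (2 / pi) * acos(clamp_unit(-omega))
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(meta, by = "profile_id") |>
    dplyr::relocate(dplyr::any_of(c("compound", "cell_line", "dose", "time",
                                    "replicate_group")),
                    .after = "profile_id")
  new_tred_tbl(out, "tred_results")
}

as_profile_matrix <- function(profiles) {
  if (inherits(profiles, "profile_matrix")) {
    return(profiles)
  }
  if (is.matrix(profiles)) {
    return(profile_matrix(profiles))
  }
  abort_invalid("`profiles` must be a profile_matrix or a numeric matrix.")
}

#' Score, test, and flag every signature / profile pair
#'
#' The full per-pair analysis: [tred_score()] plus permutation p-values
#' (label-shuffle or degree-preserving network null), the pooled
#' experiment-wise p-value with Bonferroni adjustment across drugs, the
#' 2-SD rule, replicate-direction consistency, and the confirmatory cell
#' line check for unreplicated profiles.
#'
#' @inheritParams tred_score
#' @param n_perm Permutations per pair (default 1000).
#' @param seed Integer seed driving every permutation (default 1); child
#'   seeds are derived per (signature, profile).
#' @param alpha Nominal significance level (default 0.05).
#' @param alpha_adj Threshold on the adjusted p-value (default 0.05).
#' @param sidedness `"greater"` (default) or `"two_sided"`.
#' @param pooled_null Recompute experiment-wise p-values against the null
#'   pooled across all profiles of the signature before Bonferroni
#'   (default TRUE; raises resolution beyond 1/(n_perm+1)).
#' @param null `"label"` (default) for the standard shuffle or `"network"`
#'   for the degree-preserving coexpression-network null.
#' @param network A [coexpression_network()], required for
#'   `null = "network"`.
#' @param swap_fraction Edge fraction to rewire per network-null draw.
#' @return A `tred_results` tibble: the [tred_score()] columns plus
#'   `p_perm`, `p_pooled` (when pooling), `p_adj`, and logical flags
#'   `nominal_sig`, `two_sd`, `bonferroni_sig`, `replicate_consistent`,
#'   `unreplicated`, `confirmed`. Pooled null rd draws are attached as
#'   attribute `"null_rd"` (a per-signature list).
#' @examples
#' sim <- simulate_dataset(n_genes = 300, n_drugs = 8, k_signature_genes = 40,
#'                         seed = 1)
#' tred_permute(sim$signatures, sim$profiles, n_perm = 100, seed = 7)
#' @export
tred_permute <- function(signatures, profiles, n_perm = 1000, seed = 1,
                         alpha = 0.05, alpha_adj = 0.05,
                         sidedness = c("greater", "two_sided"),
                         pooled_null = TRUE,
                         null = c("label", "network"), network = NULL,
                         swap_fraction = 0.8,
                         min_overlap = 10, ties = "average") {
  sidedness <- match.arg(sidedness)
  null <- match.arg(null)
  if (n_perm < 100) {
    abort_invalid("`n_perm` must be at least 100.")
  }
  if (null == "network" && !inherits(network, "coexpression_network")) {
    abort_invalid("`null = \"network\"` requires a coexpression_network.")
  }
  profiles <- as_profile_matrix(profiles)
  res <- tred_score(signatures, profiles, min_overlap = min_overlap,
                    ties = ties)
  sig_tbl <- as_signature_tbl(signatures)
  scores_list <- signature_scores_list(sig_tbl)
  rank_mat <- rank_transform_profiles(profiles, ties = ties)

  sig_ids <- unique(res$signature_id)
  res$p_perm <- NA_real_
  null_pool <- vector("list", length(sig_ids))
  names(null_pool) <- sig_ids

  for (si in seq_along(sig_ids)) {
    sig_id <- sig_ids[si]
    g_full <- rank_ratio(scores_list[[sig_id]], ties = ties)
    support <- names(g_full)[names(g_full) %in% rownames(rank_mat)]
    g <- g_full[support]
    idx <- which(res$signature_id == sig_id)
    prof_ids <- res$profile_id[idx]

    if (null == "label") {
      nulls <- matrix(NA_real_, n_perm, length(prof_ids))
      for (j in seq_along(prof_ids)) {
        universe <- rank_mat[, prof_ids[j]]
        nulls[, j] <- with_seed(
          child_seed(seed, (si - 1L) * ncol(rank_mat) + j),
          null_rd_draws(g, universe, n_perm)
        )
      }
    } else {
      missing <- setdiff(support, network$nodes)
      if (length(missing)) {
        abort_invalid(sprintf(
          "signature `%s` gene(s) absent from the network: %s", sig_id,
          paste(head(missing, 5L), collapse = ", ")))
      }
      nulls <- with_seed(child_seed(seed, si), {
        draws <- matrix(NA_real_, n_perm, length(prof_ids))
        for (b in seq_len(n_perm)) {
          perm <- rewire_impl(network, g, swap_fraction)
          common <- names(perm$values)[names(perm$values) %in% rownames(rank_mat)]
          gp <- perm$values[common]
          dsub <- rank_mat[common, prof_ids, drop = FALSE]
          dn <- sqrt(colSums(dsub^2))
          dn[dn == 0] <- .Machine$double.eps
          draws[b, ] <- -drop(crossprod(dsub, gp)) / dn
        }
        draws
      })
    }

    obs <- res$rd[idx]
    res$p_perm[idx] <- vapply(seq_along(idx), function(j) {
      perm_pvalue(obs[j], nulls[, j], sidedness)
    }, numeric(1))
    null_pool[[sig_id]] <- as.vector(nulls)
  }

  res <- adjust_pvalues(res, null_rds = if (pooled_null) null_pool else NULL,
                        sidedness = sidedness)
  res$nominal_sig <- res$p_perm < alpha
  res <- res |>
    dplyr::group_by(.data$signature_id) |>
    dplyr::mutate(two_sd = two_sd_flag(.data$rd, .data$rd)) |>
    dplyr::ungroup()
  res$bonferroni_sig <- res$p_adj < alpha_adj
  res <- flag_replicates(res)
  res <- confirmatory_check(res)
  res <- new_tred_tbl(res, "tred_results")
  attr(res, "null_rd") <- null_pool
  attr(res, "config") <- list(n_perm = n_perm, seed = seed, alpha = alpha,
                              alpha_adj = alpha_adj, sidedness = sidedness,
                              pooled_null = pooled_null, null = null,
                              swap_fraction = swap_fraction,
                              min_overlap = min_overlap)
  res
}

#' KS connectivity scores for every signature / profile pair
#'
#' Baseline pattern-matching scores (see [connectivity_score()]) on the
#' same inputs as [tred_score()].
#'
#' @inheritParams tred_score
#' @return A tibble with `signature_id`, `profile_id`, perturbation
#'   metadata, `ks_up`, `ks_down`, and the connectivity `score` (positive =
#'   potential reversal).
#' @export
tred_ks <- function(signatures, profiles, ties = "average") {
  sig_tbl <- as_signature_tbl(signatures)
  profiles <- as_profile_matrix(profiles)
  scores_list <- signature_scores_list(sig_tbl)
  mat <- profiles$mat
  n <- nrow(mat)

  # drug lists: most drug-downregulated gene first, computed once per profile
  orders <- apply(mat, 2L, function(col) rownames(mat)[order(col)])

  rows <- lapply(names(scores_list), function(sig_id) {
    sig_ratio <- rank_ratio(scores_list[[sig_id]], ties = ties, center = FALSE)
    up <- names(sig_ratio)[sig_ratio < 0.5]
    down <- names(sig_ratio)[sig_ratio >= 0.5]
    per_prof <- lapply(colnames(mat), function(pid) {
      ord <- orders[, pid]
      up_pos <- which(ord %in% up)
      down_pos <- which(ord %in% down)
      if (!length(up_pos) && !length(down_pos)) {
        abort_invalid(sprintf(
          "no gene of signature `%s` is measured in profile `%s`.", sig_id, pid))
      }
      ks_up <- if (length(up_pos)) ks_enrichment(up_pos, n) else NA_real_
      ks_down <- if (length(down_pos)) ks_enrichment(down_pos, n) else NA_real_
      score <- if (length(up_pos) && length(down_pos)) {
        if (ks_up * ks_down > 0) 0 else ks_up - ks_down
      } else if (length(up_pos)) ks_up else -ks_down
      tibble(signature_id = sig_id, profile_id = pid,
             ks_up = ks_up, ks_down = ks_down, score = score)
    })
    dplyr::bind_rows(per_prof)
  })
  dplyr::bind_rows(rows) |>
    dplyr::left_join(profiles$col_meta, by = "profile_id") |>
    dplyr::relocate(dplyr::any_of(c("compound", "cell_line", "dose", "time",
                                    "replicate_group")),
                    .after = "profile_id")
}

#' Benchmark reversal distance against the KS connectivity score
#'
#' Runs both methods on a simulated dataset with known planted roles and
#' reports, per method, the rank-based AUC for separating planted reversers
#' from background profiles and the sensitivity/specificity of the 2-SD
#' call rule (score above mean + 2 SD across profiles, per signature).
#'
#' @param signatures,profiles As for [tred_score()].
#' @param truth Truth tibble from [simulate_dataset()] (columns
#'   `profile_id`, `role`).
#' @return A tibble with one row per method: `method`, `auc`,
#'   `sensitivity`, `specificity`, `n_positive`, `n_negative`.
#' @export
compare_reversal_methods <- function(signatures, profiles, truth) {
  if (!all(c("profile_id", "role") %in% names(truth))) {
    abort_invalid("`truth` must have columns `profile_id` and `role`.")
  }
  rd_tbl <- tred_score(signatures, profiles) |>
    dplyr::transmute(.data$signature_id, .data$profile_id,
                     method = "reversal_distance", score = .data$rd)
  ks_tbl <- tred_ks(signatures, profiles) |>
    dplyr::transmute(.data$signature_id, .data$profile_id,
                     method = "ks_connectivity", score = .data$score)
  both <- dplyr::bind_rows(rd_tbl, ks_tbl) |>
    dplyr::inner_join(truth[, c("profile_id", "role")], by = "profile_id") |>
    dplyr::filter(.data$role %in% c("reverser", "background")) |>
    dplyr::mutate(positive = .data$role == "reverser")
  both |>
    dplyr::group_by(.data$signature_id, .data$method) |>
    dplyr::mutate(called = .data$score > mean(.data$score) + 2 * sd(.data$score)) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      auc = rank_auc(.data$score, .data$positive),
      sensitivity = sum(.data$called & .data$positive) / sum(.data$positive),
      specificity = sum(!.data$called & !.data$positive) / sum(!.data$positive),
      n_positive = sum(.data$positive),
      n_negative = sum(!.data$positive),
      .groups = "drop"
    )
}

# Mann-Whitney AUC: probability a random positive outranks a random negative
rank_auc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
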