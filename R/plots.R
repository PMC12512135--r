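#' Volcano-style plot of reversal distances
#'
#' One point per (signature, profile): reversal distance against
#' -log10 permutation p-value (when present), colored by the 2-SD rule,
#' faceted by signature.
#'
#' @param object A `tred_results` tibble from [tred_score()] or
#'   [tred_permute()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tred_results <- function(object, ...) {
  df <- tidy.tred_results(object)
  if ("p_perm" %in% names(df)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rd,
                                          y = -log10(.data$p_perm)))
    if ("two_sd" %in% names(df)) {
      p <- p + ggplot2::aes(colour = .data$two_sd)
    }
    p <- p +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "reversal distance (rd)",
                    y = expression(-log[10] ~ "permutation p"),
                    colour = "rd > mean + 2SD")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rd)) +
      ggplot2::geom_histogram(bins = 40) +
      ggplot2::labs(x = "reversal distance (rd)", y = "profiles")
  }
  p +
    ggplot2::facet_wrap(~signature_id) +
    ggplot2::theme_minimal()
}

#' Drug x signature heatmap of prioritized reversal distances
#'
#' Mirrors the usual presentation of multi-signature repositioning runs:
#' tiles show each prioritized drug's best rd per signature (profiles that
#' do not support the signature are blank).
#'
#' @param object A `tred_prioritization` tibble from [prioritize_drugs()].
#' @param results The profile-level `tred_results` the prioritization was
#'   built from (supplies the per-signature rd values).
#' @param only_passing Show only drugs with `passes_threshold` (default
#'   TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tred_prioritization <- function(object, results, only_passing = TRUE,
                                         ...) {
  drugs <- if (only_passing) {
    object$compound[object$passes_threshold]
  } else {
    object$compound
  }
  df <- tidy.tred_results(results) |>
    dplyr::filter(.data$compound %in% drugs) |>
    dplyr::group_by(.data$compound, .data$signature_id) |>
    dplyr::summarise(best_rd = max(.data$rd),
                     supported = any(.data$nominal_sig & .data$two_sd),
                     .groups = "drop") |>
    dplyr::filter(.data$supported)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature_id, y = .data$compound,
                                   fill = .data$best_rd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "rd") +
    ggplot2::labs(x = "disease signature", y = "drug") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Null distribution of the reversal distance for one signature
#'
#' Histogram of the pooled permutation null rd draws attached to a
#' [tred_permute()] result, with the observed rd values overlaid.
#'
#' @param results A `tred_results` tibble carrying the `"null_rd"`
#'   attribute.
#' @param signature_id Which signature to plot (default: first).
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(results, signature_id = NULL) {
  nulls <- attr(results, "null_rd")
  if (is.null(nulls)) {
    abort_invalid("`results` carries no null draws; run tred_permute() first.")
  }
  signature_id <- signature_id %||% names(nulls)[1]
  df_null <- tibble(rd = nulls[[signature_id]])
  df_obs <- tidy.tred_results(results) |>
    dplyr::filter(.data$signature_id == !!signature_id)
  ggplot2::ggplot(df_null, ggplot2::aes(x = .data$rd)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(data = df_obs,
                        ggplot2::aes(xintercept = .data$rd),
                        colour = "firebrick", alpha = 0.5) +
    ggplot2::labs(title = signature_id, x = "null reversal distance",
                  y = "count") +
    ggplot2::theme_minimal()
}
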