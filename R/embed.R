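#' Embed a signature / profile pair in a shared gene space
#'
#' Rank-ratio transforms both vectors and restricts them to their common
#' gene support. The drug profile is rank-transformed over all genes it
#' measures (global ranks) and only then restricted to the signature's
#' genes; the signature is rank-transformed over its own genes. Signature
#' genes not measured in the profile are dropped and counted.
#'
#' @param sig A `disease_signature` or named numeric vector of raw
#'   association scores.
#' @param prof A named numeric vector of raw per-gene profile scores (all
#'   genes the experiment measured), or a `profile_matrix` together with
#'   `profile_id`.
#' @param min_overlap Minimum number of shared genes required (default 10);
#'   below this an insufficient-overlap error is raised.
#' @param profile_id When `prof` is a `profile_matrix`, which column to use.
#' @param ties Tie method for ranking (default `"average"`).
#'
#' @return An object of class `embedded_pair`: list with `support` (shared
#'   gene ids), `g` and `d` (centered rank-ratio vectors on the support),
#'   `d_full` (the profile's full centered rank vector, the permutation
#'   universe), `n_dropped`, `g_norm`, `d_norm`, and the two ids.
#'
#' @examples
#' sig <- c(a = 2.0, b = -1.5, c = 0.3)
#' prof <- setNames(rnorm(26), letters)
#' embed_pair(sig, prof, min_overlap = 3)
#' @export
embed_pair <- function(sig, prof, min_overlap = 10, profile_id = NULL,
                       ties = "average") {
  sig_id <- "signature"
  if (inherits(sig, "disease_signature")) {
    sig_id <- sig$signature_id
    sig <- sig$scores
  }
  prof_id <- profile_id %||% "profile"
  if (inherits(prof, "profile_matrix")) {
    if (is.null(profile_id)) {
      abort_invalid("supply `profile_id` when `prof` is a profile_matrix.")
    }
    prof <- profile_scores(prof, profile_id)
  }
  check_named_scores(sig, "signature scores")
  check_named_scores(prof, "profile scores")

  g_full <- rank_ratio(sig, ties = ties)
  d_full <- rank_ratio(prof, ties = ties)
  support <- names(g_full)[names(g_full) %in% names(d_full)]
  n_dropped <- length(g_full) - length(support)
  if (length(support) < min_overlap) {
    abort_overlap(sprintf(
      "only %d genes shared between signature `%s` and profile `%s` (min_overlap = %d).",
      length(support), sig_id, prof_id, min_overlap
    ))
  }
  g <- g_full[support]
  d <- d_full[support]
  gn <- l2norm(g)
  dn <- l2norm(d)
  if (gn == 0 || dn == 0) {
    abort_degenerate(sprintf(
      "zero-norm embedded vector for signature `%s` / profile `%s`.", sig_id, prof_id
    ))
  }
  structure(
    list(
      signature_id = sig_id, profile_id = prof_id,
      support = support, g = g, d = d,
      d_full = d_full, n_dropped = n_dropped,
      g_norm = gn, d_norm = dn
    ),
    class = "embedded_pair"
  )
}

#' @export
print.embedded_pair <- function(x, ...) {
  cat(sprintf(
    "<embedded_pair> %s ~ %s: %d shared genes (%d dropped), ||g|| = %.4f, ||d|| = %.4f\n",
    x$signature_id, x$profile_id, length(x$support), x$n_dropped, x$g_norm, x$d_norm
  ))
  invisible(x)
}

#' @export
tidy.embedded_pair <- function(x, ...) {
  tibble(gene = x$support, g = unname(x$g), d = unname(x$d))
}
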