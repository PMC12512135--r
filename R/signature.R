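#' Construct a disease signature
#'
#' A disease signature is a vector of per-gene association scores for one
#' disease in one tissue or dataset: TWAS Z-scores (genetically anchored) or
#' DGE log fold changes (observed case-vs-control changes).
#'
#' @param scores Named numeric vector: gene identifier -> association score.
#' @param signature_id Label for the signature (e.g. `"lung_twas"`).
#' @param source_kind `"TWAS"` or `"DGE"`.
#' @param tissue Optional tissue / dataset label.
#'
#' @return An object of class `disease_signature`.
#' @examples
#' disease_signature(c(TYK2 = 4.1, OAS1 = -3.2, IFNAR2 = 2.0),
#'                   "blood_twas", "TWAS", tissue = "whole blood")
#' @export
disease_signature <- function(scores, signature_id, source_kind = c("TWAS", "DGE"),
                              tissue = NA_character_) {
  source_kind <- match.arg(source_kind)
  check_named_scores(scores, "signature scores")
  structure(
    list(
      signature_id = as.character(signature_id),
      source_kind = source_kind,
      tissue = as.character(tissue),
      scores = scores
    ),
    class = "disease_signature"
  )
}

#' @export
print.disease_signature <- function(x, ...) {
  cat(sprintf(
    "<disease_signature> %s (%s%s): %d genes, score range [%.3g, %.3g]\n",
    x$signature_id, x$source_kind,
    if (is.na(x$tissue)) "" else paste0(", ", x$tissue),
    length(x$scores), min(x$scores), max(x$scores)
  ))
  invisible(x)
}

#' @export
tidy.disease_signature <- function(x, ...) {
  tibble(
    signature_id = x$signature_id,
    source_kind = x$source_kind,
    tissue = x$tissue,
    gene = names(x$scores),
    score = unname(x$scores)
  )
}

#' @export
as_tibble.disease_signature <- function(x, ...) tidy.disease_signature(x)

# Normalise the user-facing "signatures" argument to a long tibble with
# columns signature_id, source_kind, gene, score. Accepts a single
# disease_signature, a list of them, or an already-long data frame.
as_signature_tbl <- function(signatures) {
  if (inherits(signatures, "disease_signature")) {
    return(tidy.disease_signature(signatures))
  }
  if (is.list(signatures) && !is.data.frame(signatures) &&
      all(vapply(signatures, inherits, logical(1), "disease_signature"))) {
    return(dplyr::bind_rows(lapply(signatures, tidy.disease_signature)))
  }
  if (is.data.frame(signatures)) {
    need <- c("signature_id", "gene", "score")
    miss <- setdiff(need, names(signatures))
    if (length(miss)) {
      abort_invalid(sprintf(
        "signature table is missing column(s): %s", paste(miss, collapse = ", ")
      ))
    }
    out <- as_tibble(signatures)
    if (!"source_kind" %in% names(out)) {
      out$source_kind <- NA_character_
    }
    if (!"tissue" %in% names(out)) {
      out$tissue <- NA_character_
    }
    dup <- out |>
      dplyr::count(.data$signature_id, .data$gene) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(dup)) {
      abort_invalid(sprintf(
        "duplicate gene(s) within signature(s): %s",
        paste(head(paste0(dup$signature_id, "/", dup$gene), 5L), collapse = ", ")
      ))
    }
    if (!all(is.finite(out$score))) {
      abort_invalid("all signature scores must be finite.")
    }
    return(out)
  }
  abort_invalid(
    "`signatures` must be a disease_signature, a list of them, or a data frame."
  )
}

# Split a signature tibble into a named list of named score vectors,
# preserving first-appearance order of signatures.
signature_scores_list <- function(sig_tbl) {
  ids <- unique(sig_tbl$signature_id)
  out <- lapply(ids, function(id) {
    sub <- sig_tbl[sig_tbl$signature_id == id, ]
    setNames(sub$score, sub$gene)
  })
  names(out) <- ids
  out
}

signature_kinds <- function(sig_tbl) {
  kinds <- sig_tbl |>
    dplyr::distinct(.data$signature_id, .data$source_kind)
  setNames(kinds$source_kind, kinds$signature_id)
}
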