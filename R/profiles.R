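#' Construct a drug response profile matrix
#'
#' Container for a genes x experiments matrix of differential-expression
#' scores (LINCS Level-5-style) with per-column perturbation metadata. The
#' replicate group key is `compound x cell_line x dose x time`, the fields
#' LINCS technical replicates share.
#'
#' @param mat Numeric matrix, genes in rows (unique rownames = gene ids),
#'   experiments in columns (unique colnames = profile ids).
#' @param col_meta Data frame with one row per column of `mat`; must contain
#'   `profile_id` matching `colnames(mat)` plus `compound`, `cell_line`,
#'   `dose`, `time` (missing metadata columns are filled with `"NA"`).
#' @param row_meta Optional data frame of per-gene annotations (first column
#'   or `gene` column must match rownames).
#'
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(mat, col_meta = NULL, row_meta = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    abort_invalid("`mat` must be a numeric matrix.")
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    abort_invalid("`mat` must have unique gene identifiers as rownames.")
  }
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat))) {
    abort_invalid("`mat` must have unique profile identifiers as colnames.")
  }
  if (!all(is.finite(mat))) {
    abort_invalid("all profile scores must be finite.")
  }
  if (is.null(col_meta)) {
    col_meta <- tibble(profile_id = colnames(mat))
  }
  col_meta <- as_tibble(col_meta)
  if (!"profile_id" %in% names(col_meta)) {
    abort_invalid("`col_meta` must contain a `profile_id` column.")
  }
  if (!identical(sort(col_meta$profile_id), sort(colnames(mat))) ||
      nrow(col_meta) != ncol(mat)) {
    abort_invalid("`col_meta$profile_id` must match the matrix columns exactly.")
  }
  col_meta <- col_meta[match(colnames(mat), col_meta$profile_id), ]
  for (f in c("compound", "cell_line", "dose", "time")) {
    if (!f %in% names(col_meta)) {
      col_meta[[f]] <- "NA"
    }
    if (anyNA(col_meta[[f]])) {
      abort_invalid(sprintf("column metadata field `%s` has missing values.", f))
    }
  }
  col_meta$replicate_group <- replicate_group_key(col_meta)
  structure(
    list(mat = mat, col_meta = col_meta, row_meta = row_meta),
    class = "profile_matrix"
  )
}

# replicate_group is a deterministic function of (compound, cell_line, dose, time)
replicate_group_key <- function(meta) {
  paste(meta$compound, meta$cell_line, meta$dose, meta$time, sep = "|")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "<profile_matrix> %d genes x %d profiles (%d compounds, %d cell lines)\n",
    nrow(x$mat), ncol(x$mat),
    dplyr::n_distinct(x$col_meta$compound),
    dplyr::n_distinct(x$col_meta$cell_line)
  ))
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$mat)

#' Subset a profile matrix by profile or gene
#'
#' @param x A `profile_matrix`.
#' @param i Gene identifiers or indices (rows).
#' @param j Profile identifiers or indices (columns).
#' @param ... Unused.
#' @return A `profile_matrix` restricted to the requested rows/columns.
#' @export
`[.profile_matrix` <- function(x, i, j, ...) {
  mat <- x$mat
  if (!missing(i)) mat <- mat[i, , drop = FALSE]
  if (!missing(j)) mat <- mat[, j, drop = FALSE]
  profile_matrix(mat, x$col_meta[match(colnames(mat), x$col_meta$profile_id), ],
                 x$row_meta)
}

#' @export
tidy.profile_matrix <- function(x, ...) {
  long <- as_tibble(x$mat, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "profile_id", values_to = "score")
  dplyr::left_join(long, x$col_meta, by = "profile_id")
}

#' @export
as_tibble.profile_matrix <- function(x, ...) tidy.profile_matrix(x)

#' @export
glance.profile_matrix <- function(x, ...) {
  tibble(
    n_genes = nrow(x$mat),
    n_profiles = ncol(x$mat),
    n_compounds = dplyr::n_distinct(x$col_meta$compound),
    n_cell_lines = dplyr::n_distinct(x$col_meta$cell_line),
    n_replicate_groups = dplyr::n_distinct(x$col_meta$replicate_group)
  )
}

#' Extract one profile as a named score vector
#'
#' @param profiles A `profile_matrix`.
#' @param profile_id Column identifier.
#' @return Named numeric vector of per-gene scores.
#' @export
profile_scores <- function(profiles, profile_id) {
  if (!inherits(profiles, "profile_matrix")) {
    abort_invalid("`profiles` must be a profile_matrix.")
  }
  if (!profile_id %in% colnames(profiles$mat)) {
    abort_invalid(sprintf("unknown profile_id `%s`.", profile_id))
  }
  profiles$mat[, profile_id]
}

# Centered rank-ratio transform of every column, over the full measured gene
# set of the profile (drug ranks are global, before any signature
# restriction).
rank_transform_profiles <- function(profiles, ties = "average") {
  mat <- profiles$mat
  out <- apply(mat, 2L, function(col) {
    rank(-col, ties.method = ties) / length(col) - 0.5
  })
  rownames(out) <- rownames(mat)
  out
}
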