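#' Read a GCT 1.3 profile matrix
#'
#' Parses the tab-delimited GCT 1.3 dialect used for LINCS Level-5-style
#' matrices: a `#1.3` version line; a dimension line
#' `nrow ncol n_row_meta n_col_meta`; a header row (`id`, row-metadata
#' names, column ids); `n_col_meta` column-metadata rows; then `nrow` data
#' rows. Column-metadata headers are mapped onto the perturbation fields
#' via `col_mapping`. Gene identifiers are treated as opaque strings.
#'
#' @param path Path to a GCT 1.3 text file.
#' @param col_mapping Named character vector mapping the canonical fields
#'   `compound`, `cell_line`, `dose`, `time` to the file's column-metadata
#'   header names.
#' @return A [profile_matrix()].
#' @export
read_gct <- function(path,
                     col_mapping = c(compound = "compound",
                                     cell_line = "cell_line",
                                     dose = "dose", time = "time")) {
  if (!file.exists(path)) {
    abort_format(sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) {
    abort_format(sprintf("%s: truncated file (only %d line(s)).", path, length(lines)))
  }
  if (trimws(lines[1]) != "#1.3") {
    abort_format(sprintf("%s, line 1: expected version line '#1.3', got '%s'.",
                         path, lines[1]))
  }
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(dims) != 4L || anyNA(suppressWarnings(as.integer(dims)))) {
    abort_format(sprintf(
      "%s, line 2: expected four integers (nrow ncol nrmeta ncmeta).", path))
  }
  dims <- as.integer(dims)
  nr <- dims[1]; nc <- dims[2]; nrm <- dims[3]; ncm <- dims[4]
  expected_lines <- 3L + ncm + nr
  if (length(lines) < expected_lines) {
    abort_format(sprintf(
      "%s: truncated file; expected %d lines for the declared dimensions, found %d (first missing line: %d).",
      path, expected_lines, length(lines), length(lines) + 1L))
  }
  split_row <- function(i, what) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 1L + nrm + nc) {
      abort_format(sprintf(
        "%s, line %d: %s has %d fields, expected %d.",
        path, i, what, length(f), 1L + nrm + nc))
    }
    f
  }
  header <- split_row(3L, "header row")
  rmeta_names <- if (nrm > 0) header[2:(1 + nrm)] else character()
  col_ids <- header[(2 + nrm):(1 + nrm + nc)]
  if (anyDuplicated(col_ids)) {
    abort_format(sprintf("%s, line 3: duplicate column id(s): %s", path,
                         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", ")))
  }

  cmeta <- list()
  for (k in seq_len(ncm)) {
    f <- split_row(3L + k, "column-metadata row")
    cmeta[[f[1]]] <- f[(2 + nrm):(1 + nrm + nc)]
  }

  data_lines <- lines[(3L + ncm + 1L):(3L + ncm + nr)]
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 1L + nrm + nc)) {
    bad <- which(nf != 1L + nrm + nc)[1]
    abort_format(sprintf("%s, line %d: data row has %d fields, expected %d.",
                         path, 3L + ncm + bad, nf[bad], 1L + nrm + nc))
  }
  gene_ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    abort_format(sprintf("%s: duplicate gene id(s): %s", path,
                         paste(head(dup, 5L), collapse = ", ")))
  }
  mat <- matrix(NA_real_, nr, nc, dimnames = list(gene_ids, col_ids))
  for (i in seq_len(nr)) {
    vals <- suppressWarnings(as.numeric(fields[[i]][(2 + nrm):(1 + nrm + nc)]))
    if (anyNA(vals)) {
      abort_format(sprintf("%s, line %d: non-numeric data value.",
                           path, 3L + ncm + i))
    }
    mat[i, ] <- vals
  }
  row_meta <- NULL
  if (nrm > 0) {
    row_meta <- as_tibble(setNames(
      lapply(seq_len(nrm), function(k) vapply(fields, `[[`, character(1), 1L + k)),
      rmeta_names
    ))
    row_meta <- dplyr::bind_cols(tibble(gene = gene_ids), row_meta)
  }

  col_meta <- tibble(profile_id = col_ids)
  for (field in names(col_mapping)) {
    src <- col_mapping[[field]]
    col_meta[[field]] <- if (src %in% names(cmeta)) cmeta[[src]] else "NA"
  }
  extra <- setdiff(names(cmeta), col_mapping)
  for (nm in extra) {
    col_meta[[nm]] <- cmeta[[nm]]
  }
  profile_matrix(mat, col_meta, row_meta)
}

#' Write a GCT 1.3 profile matrix
#'
#' Deterministic writer for the format read by [read_gct()]. Numeric values
#' are written with 15 significant digits, so a read/write round trip
#' reproduces the matrix to better than 1e-9 relative error.
#'
#' @param profiles A [profile_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(profiles, path) {
  if (!inherits(profiles, "profile_matrix")) {
    abort_invalid("`profiles` must be a profile_matrix.")
  }
  mat <- profiles$mat
  meta <- profiles$col_meta
  cmeta_fields <- setdiff(names(meta), c("profile_id", "replicate_group"))
  rmeta <- profiles$row_meta
  rmeta_names <- if (!is.null(rmeta)) setdiff(names(rmeta), "gene") else character()
  nrm <- length(rmeta_names)

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(paste(nrow(mat), ncol(mat), nrm, length(cmeta_fields), sep = "\t"), con)
  writeLines(paste(c("id", rmeta_names, colnames(mat)), collapse = "\t"), con)
  for (f in cmeta_fields) {
    writeLines(paste(c(f, rep("na", nrm), as.character(meta[[f]])),
                     collapse = "\t"), con)
  }
  num <- formatC(mat, digits = 15, format = "g")
  for (i in seq_len(nrow(mat))) {
    rm_vals <- if (nrm > 0) as.character(unlist(rmeta[i, rmeta_names])) else character()
    writeLines(paste(c(rownames(mat)[i], rm_vals, num[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}
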