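#' Read a disease signature table
#'
#' Tab-separated file with a header; one row per gene with its association
#' score (TWAS Z-score or DGE log fold change).
#'
#' @param path Path to the TSV file.
#' @param kind `"TWAS"` or `"DGE"`.
#' @param signature_id Label for the signature; defaults to the file name
#'   without extension.
#' @param gene_col,score_col Column names holding the gene identifier and
#'   the score (defaults `"gene"`, `"score"`).
#' @param tissue Optional tissue / dataset label.
#' @return A [disease_signature()].
#' @export
read_signature <- function(path, kind = c("TWAS", "DGE"), signature_id = NULL,
                           gene_col = "gene", score_col = "score",
                           tissue = NA_character_) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort_format(sprintf("file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      colClasses = "character"),
    error = function(e) abort_format(sprintf("%s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0L) {
    abort_invalid(sprintf("%s: signature file contains no gene rows.", path))
  }
  miss <- setdiff(c(gene_col, score_col), names(df))
  if (length(miss)) {
    abort_format(sprintf("%s: missing column(s): %s", path,
                         paste(miss, collapse = ", ")))
  }
  genes <- df[[gene_col]]
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort_format(sprintf("%s: duplicated gene(s): %s", path,
                         paste(head(dup, 5L), collapse = ", ")))
  }
  scores <- suppressWarnings(as.numeric(df[[score_col]]))
  if (anyNA(scores)) {
    bad <- genes[which(is.na(scores))[1]]
    abort_format(sprintf("%s: non-numeric score for gene %s.", path, bad))
  }
  disease_signature(setNames(scores, genes),
                    signature_id %||% sub("\\.[^.]*$", "", basename(path)),
                    kind, tissue)
}

#' Read a coexpression network edge list
#'
#' Two tab-separated gene columns per line (undirected edges). A header
#' line is detected and skipped when its fields are `gene1` / `gene2`
#' (case-insensitive). Self-loops and duplicate edges are format errors.
#'
#' @param path Path to the edge-list file.
#' @return A [coexpression_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    abort_format(sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort_invalid(sprintf("%s: empty edge list.", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(trimws(fields[[1]])), c("gene1", "gene2"))) {
    fields <- fields[-1]
    offset <- 1L
  } else {
    offset <- 0L
  }
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1]
    abort_format(sprintf("%s, line %d: expected two tab-separated gene columns, found %d.",
                         path, bad + offset, nf[bad]))
  }
  edges <- matrix(unlist(fields), ncol = 2L, byrow = TRUE)
  coexpression_network(edges)
}

#' Write a coexpression network edge list
#'
#' @param net A [coexpression_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  writeLines(c("gene1\tgene2",
               paste(net$edges[, 1], net$edges[, 2], sep = "\t")), path)
  invisible(path)
}

results_columns <- c("signature_id", "profile_id", "compound", "cell_line",
                     "omega", "rd", "d_norm", "p_perm", "p_adj", "flags")

flag_names <- c("nominal_sig", "two_sd", "replicate_consistent",
                "bonferroni_sig")

# collapse logical flag columns into a comma-joined string column
collapse_flags <- function(results) {
  have <- intersect(flag_names, names(results))
  if (!"bonferroni_sig" %in% names(results) && "p_adj" %in% names(results)) {
    results$bonferroni_sig <- results$p_adj < 0.05
    have <- union(have, "bonferroni_sig")
  }
  apply(as.matrix(results[have]), 1L, function(r) {
    paste(have[which(as.logical(r))], collapse = ",")
  })
}

#' Write a results table
#'
#' Deterministic TSV writer: columns `signature_id, profile_id, compound,
#' cell_line, omega, rd, d_norm, p_perm, p_adj, flags`, sorted by
#' `signature_id` then decreasing rd. The `flags` column comma-joins the
#' logical flags set for the row.
#'
#' @param results Results tibble from [tred_permute()] (or [tred_score()],
#'   in which case the p-value and flag columns are written as `NA`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- as_tibble(results)
  for (col in c("p_perm", "p_adj")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  if (!"cell_line" %in% names(out)) out[["cell_line"]] <- NA_character_
  out$flags <- if (any(flag_names %in% names(out))) collapse_flags(out) else ""
  out <- out[order(out$signature_id, -out$rd), results_columns]
  num_cols <- c("omega", "rd", "d_norm", "p_perm", "p_adj")
  for (col in num_cols) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A `tred_results` tibble; the `flags` string is expanded back
#'   into logical columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    abort_format(sprintf("file not found: %s", path))
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  miss <- setdiff(results_columns, names(df))
  if (length(miss)) {
    abort_format(sprintf("%s: missing column(s): %s", path,
                         paste(miss, collapse = ", ")))
  }
  out <- as_tibble(df)
  for (col in c("omega", "rd", "d_norm", "p_perm", "p_adj")) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  flags <- strsplit(out$flags, ",", fixed = TRUE)
  for (fl in flag_names) {
    out[[fl]] <- vapply(flags, function(x) fl %in% x, logical(1))
  }
  new_tred_tbl(out, "tred_results")
}

#' Read / write a run configuration
#'
#' YAML (or JSON) configuration capturing the thresholds, seeds and
#' column-name mappings of a run: `alpha`, `alpha_adj`, `n_perm`,
#' `two_sd_rule`, `swap_fraction`, `min_signatures`,
#' `require_twas_and_dge`, `min_overlap`, `seed`, `col_mapping`.
#' Missing fields are filled with the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_format(sprintf("file not found: %s", path))
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) {
    abort_format(sprintf("%s: configuration must be a mapping.", path))
  }
  modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @param cfg Named list of configuration values.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- modifyList(default_run_config(), as.list(cfg))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    alpha = 0.05,
    alpha_adj = 0.05,
    n_perm = 1000L,
    two_sd_rule = TRUE,
    swap_fraction = 0.8,
    min_signatures = 1L,
    require_twas_and_dge = FALSE,
    min_overlap = 10L,
    pooled_null = TRUE,
    sidedness = "greater",
    seed = 1L,
    col_mapping = list(compound = "compound", cell_line = "cell_line",
                       dose = "dose", time = "time")
  )
}
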