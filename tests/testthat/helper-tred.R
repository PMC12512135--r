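# Shared fixtures and independent oracles.

# random raw-score vectors with unique gene names
random_scores <- function(n, genes = sprintf("g%04d", seq_len(n))) {
  setNames(rnorm(n), genes)
}

# a random embedded pair whose signature genes are a subset of the profile's
random_embedded_pair <- function(n_sig = 30, n_prof = 200, min_overlap = 10) {
  prof <- random_scores(n_prof)
  sig_genes <- sample(names(prof), n_sig)
  sig <- setNames(rnorm(n_sig), sig_genes)
  embed_pair(sig, prof, min_overlap = min_overlap)
}

# independent cosine: plain dot products, no shared code path
oracle_cosine <- function(g, d) {
  sum(g * d) / (sqrt(sum(g * g)) * sqrt(sum(d * d)))
}

# central finite difference of omega in one coordinate of d (or g)
fd_domega <- function(g, d, i, wrt = c("d", "g"), h = 1e-6) {
  wrt <- match.arg(wrt)
  up <- if (wrt == "d") {
    dp <- d; dp[i] <- dp[i] + h
    oracle_cosine(g, dp)
  } else {
    gp <- g; gp[i] <- gp[i] + h
    oracle_cosine(gp, d)
  }
  dn <- if (wrt == "d") {
    dm <- d; dm[i] <- dm[i] - h
    oracle_cosine(g, dm)
  } else {
    gm <- g; gm[i] <- gm[i] - h
    oracle_cosine(gm, d)
  }
  (up - dn) / (2 * h)
}

# brute-force KS enrichment via a full scan of the empirical CDF difference,
# independent of the tag-position formulas in the package
oracle_ks <- function(positions, n) {
  is_tag <- seq_len(n) %in% positions
  t <- sum(is_tag)
  f_tag <- cumsum(is_tag) / t
  i <- seq_len(n)
  a <- max(f_tag - i / n)
  b <- max(i / n - c(0, f_tag[-n]))
  if (a >= b) a else -b
}

# tiny GCT writer used only to build on-disk fixtures in tests
make_gct_fixture <- function(path, mat, compound, cell_line,
                             dose = rep("10uM", ncol(mat)),
                             time = rep("24h", ncol(mat))) {
  lines <- c(
    "#1.3",
    paste(nrow(mat), ncol(mat), 0, 4, sep = "\t"),
    paste(c("id", colnames(mat)), collapse = "\t"),
    paste(c("compound", compound), collapse = "\t"),
    paste(c("cell_line", cell_line), collapse = "\t"),
    paste(c("dose", dose), collapse = "\t"),
    paste(c("time", time), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], format(mat[i, ], digits = 12)), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  path
}
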