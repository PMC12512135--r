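#' Simulate signatures, drug response profiles, and planted reversers
#'
#' Generates a complete synthetic study: disease signatures with Gaussian
#' per-gene association scores, a genes x experiments drug response
#' profile matrix with i.i.d. standard-normal background scores, and
#' planted drugs whose scores on each signature's support are
#' `-effect * signature + sqrt(1 - effect^2) * noise` (reversers) or the
#' `+effect` analogue (mimickers), so `effect` is the target
#' (anti-)correlation between the planted drug and the signature.
#' Replicates share a compound's latent mean profile plus independent
#' Gaussian noise; planted constructions are applied in every cell line,
#' so confirmatory cell lines carry the same direction. Signature gene
#' sets are disjoint when they fit inside the gene universe, otherwise
#' sampled independently.
#'
#' @param n_genes Genes measured by every profile (default 2000).
#' @param n_drugs Compounds (default 200).
#' @param k_signature_genes Genes per signature (default 150).
#' @param effect Planted (anti-)correlation in \[0, 1\] (default 0.8).
#' @param n_signatures Number of disease signatures (default 1); TWAS and
#'   DGE kinds are interleaved (TWAS first).
#' @param n_replicates Technical replicates per compound x cell line
#'   (default 1).
#' @param n_cell_lines Cell lines per compound (default 1).
#' @param n_reversers,n_mimickers Planted drug counts (defaults 1, 0).
#' @param replicate_sd Standard deviation of replicate noise around the
#'   latent profile (default 0.3; set 0 for noise-free replicates).
#' @param seed Integer seed (optional but recommended).
#' @return A list with `signatures` (long tibble), `profiles`
#'   ([profile_matrix()]), and `truth` (tibble with `profile_id`,
#'   `compound`, `cell_line`, `replicate`, `role`, `effect`).
#' @examples
#' sim <- simulate_dataset(n_genes = 500, n_drugs = 20, k_signature_genes = 50,
#'                         seed = 42)
#' sim$truth[sim$truth$role != "background", ]
#' @export
simulate_dataset <- function(n_genes = 2000, n_drugs = 200,
                             k_signature_genes = 150, effect = 0.8,
                             n_signatures = 1, n_replicates = 1,
                             n_cell_lines = 1, n_reversers = 1,
                             n_mimickers = 0, replicate_sd = 0.3,
                             seed = NULL) {
  if (k_signature_genes > n_genes) {
    abort_invalid("`k_signature_genes` cannot exceed `n_genes`.")
  }
  if (k_signature_genes < 2 || n_genes < 2 || n_drugs < 1) {
    abort_invalid("need at least 2 genes per signature and 1 drug.")
  }
  if (effect < 0 || effect > 1) {
    abort_invalid("`effect` must lie in [0, 1].")
  }
  if (n_reversers + n_mimickers > n_drugs) {
    abort_invalid("more planted drugs than `n_drugs`.")
  }
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    kinds <- rep(c("TWAS", "DGE"), length.out = n_signatures)
    disjoint <- n_signatures * k_signature_genes <= n_genes
    pool <- if (disjoint) sample(genes) else NULL
    sig_rows <- lapply(seq_len(n_signatures), function(s) {
      sg <- if (disjoint) {
        pool[((s - 1) * k_signature_genes + 1):(s * k_signature_genes)]
      } else {
        sample(genes, k_signature_genes)
      }
      tibble(
        signature_id = sprintf("sig%02d_%s", s, tolower(kinds[s])),
        source_kind = kinds[s],
        gene = sg,
        score = rnorm(k_signature_genes)
      )
    })
    signatures <- dplyr::bind_rows(sig_rows)
    sig_scores <- signature_scores_list(signatures)

    compounds <- sprintf("drug%04d", seq_len(n_drugs))
    roles <- c(rep("reverser", n_reversers), rep("mimicker", n_mimickers),
               rep("background", n_drugs - n_reversers - n_mimickers))
    cells <- sprintf("CL%02d", seq_len(n_cell_lines))

    n_cols <- n_drugs * n_cell_lines * n_replicates
    mat <- matrix(NA_real_, n_genes, n_cols, dimnames = list(genes, NULL))
    meta <- vector("list", n_cols)
    truth <- vector("list", n_cols)
    col <- 0L
    for (di in seq_len(n_drugs)) {
      for (ci in seq_len(n_cell_lines)) {
        latent <- rnorm(n_genes)
        if (roles[di] != "background" && effect > 0) {
          sgn <- if (roles[di] == "reverser") -1 else 1
          for (sv in sig_scores) {
            sg <- names(sv)
            latent[match(sg, genes)] <-
              sgn * effect * unname(sv) + sqrt(1 - effect^2) * rnorm(length(sv))
          }
        }
        for (ri in seq_len(n_replicates)) {
          col <- col + 1L
          obs <- latent + if (replicate_sd > 0) {
            replicate_sd * rnorm(n_genes)
          } else 0
          mat[, col] <- obs
          pid <- sprintf("%s_%s_r%d", compounds[di], cells[ci], ri)
          meta[[col]] <- tibble(
            profile_id = pid, compound = compounds[di],
            cell_line = cells[ci], dose = "10uM", time = "24h",
            replicate = sprintf("r%d", ri)
          )
          truth[[col]] <- tibble(
            profile_id = pid, compound = compounds[di],
            cell_line = cells[ci], replicate = sprintf("r%d", ri),
            role = roles[di], effect = if (roles[di] == "background") 0 else effect
          )
        }
      }
    }
    meta <- dplyr::bind_rows(meta)
    colnames(mat) <- meta$profile_id
    list(
      signatures = signatures,
      profiles = profile_matrix(mat, meta),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Simulate a coexpression network
#'
#' Configuration-model-style random graph: node degrees are drawn from a
#' Poisson distribution with the requested mean (zero degrees bumped to 1,
#' parity fixed), then wired into a simple graph — no self-loops, no
#' multi-edges — via [igraph::sample_degseq()].
#'
#' @param n_genes Number of nodes; identifiers match those of
#'   [simulate_dataset()] (`g00001`, ...).
#' @param mean_degree Target mean degree (default 4; must be >= 1).
#' @param seed Integer seed.
#' @return A [coexpression_network()].
#' @export
simulate_network <- function(n_genes, mean_degree = 4, seed = NULL) {
  if (mean_degree < 1) {
    abort_invalid("`mean_degree` must be at least 1.")
  }
  if (n_genes < 4) {
    abort_invalid("`n_genes` must be at least 4.")
  }
  with_seed(seed, {
    degs <- rpois(n_genes, mean_degree)
    degs[degs == 0] <- 1L
    degs[degs >= n_genes] <- n_genes - 1L
    if (sum(degs) %% 2 == 1) {
      degs[which.min(degs)] <- degs[which.min(degs)] + 1L
    }
    graph <- tryCatch(
      igraph::sample_degseq(degs, method = "fast.heur.simple"),
      error = function(e) {
        abort_invalid(sprintf("infeasible degree sequence: %s",
                              conditionMessage(e)))
      }
    )
    genes <- sprintf("g%05d", seq_len(n_genes))
    el <- igraph::as_edgelist(graph, names = FALSE)
    coexpression_network(
      cbind(genes[el[, 1]], genes[el[, 2]]),
      nodes = genes
    )
  })
}
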