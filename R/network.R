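#' Construct a coexpression network
#'
#' Undirected gene-gene graph used by the degree-preserving permutation
#' null. Self-loops and multi-edges are rejected.
#'
#' @param edges Two-column character matrix or data frame of gene pairs.
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the genes appearing in `edges`. Edges referencing unknown nodes are an
#'   error when `nodes` is supplied.
#' @return An object of class `coexpression_network` with fields `nodes`
#'   and `edges` (two-column character matrix).
#' @export
coexpression_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) {
    edges <- as.matrix(edges[, 1:2])
  }
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    abort_format("`edges` must have exactly two columns (gene pairs).")
  }
  storage.mode(edges) <- "character"
  if (nrow(edges) == 0L) {
    abort_invalid("the network must contain at least one edge.")
  }
  if (any(edges[, 1] == edges[, 2])) {
    bad <- which(edges[, 1] == edges[, 2])[1]
    abort_format(sprintf("self-loop at edge %d (%s).", bad, edges[bad, 1]))
  }
  keys <- edge_keys(edges)
  if (anyDuplicated(keys)) {
    abort_format(sprintf(
      "duplicate edge(s): %s",
      paste(head(unique(keys[duplicated(keys)]), 3L), collapse = ", ")
    ))
  }
  found <- sort(unique(as.vector(edges)))
  if (is.null(nodes)) {
    nodes <- found
  } else {
    nodes <- as.character(nodes)
    unknown <- setdiff(found, nodes)
    if (length(unknown)) {
      abort_format(sprintf("edge references unknown node(s): %s",
                           paste(head(unknown, 5L), collapse = ", ")))
    }
  }
  dimnames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "coexpression_network")
}

edge_keys <- function(edges) {
  paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]), sep = "\r")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d nodes, %d edges, mean degree %.2f\n",
              length(x$nodes), nrow(x$edges),
              2 * nrow(x$edges) / length(x$nodes)))
  invisible(x)
}

#' Degree sequence of a network
#'
#' @param net A `coexpression_network`.
#' @return Named integer vector of node degrees (all nodes, zeros included).
#' @export
degree_sequence <- function(net) {
  tab <- table(factor(as.vector(net$edges), levels = net$nodes))
  setNames(as.integer(tab), net$nodes)
}

#' @export
tidy.coexpression_network <- function(x, ...) {
  tibble(gene1 = x$edges[, 1], gene2 = x$edges[, 2])
}

#' Degree-preserving rewiring with an accumulated value permutation
#'
#' Randomizes the network by double edge swaps: two edges a-b and c-d with
#' four distinct nodes are rewired to a-c and b-d, rejected if either new
#' edge already exists. Every node keeps its degree exactly. Each accepted
#' swap also transposes the supplied per-node values at b and d, so the
#' accumulated transpositions yield a permutation of the values that
#' respects the network's structure — the degree-preserving null for the
#' reversal distance. Rewiring stops once at least
#' `ceiling(swap_fraction * |E|)` distinct original edges have been
#' rewired, or after `100 * |E|` attempts (then a warning reports the
#' achieved fraction).
#'
#' @param net A `coexpression_network`.
#' @param values Named numeric vector of per-node values (e.g. a signature's
#'   centered rank ratios on its genes). Names must be a subset of the
#'   network's nodes; nodes without a value participate in rewiring and may
#'   receive values through transpositions.
#' @param swap_fraction Proportion of original edges that must be rewired
#'   (default 0.8).
#' @param seed Optional integer seed.
#' @return A list with `net` (rewired `coexpression_network`), `values`
#'   (the permuted assignment: named numeric over nodes holding a value),
#'   `achieved_fraction`, `n_swaps`, and `converged`.
#' @export
rewire_preserving_degree <- function(net, values, swap_fraction = 0.8,
                                     seed = NULL) {
  if (!inherits(net, "coexpression_network")) {
    abort_invalid("`net` must be a coexpression_network.")
  }
  if (swap_fraction <= 0 || swap_fraction > 1) {
    abort_invalid("`swap_fraction` must be in (0, 1].")
  }
  if (!is.null(values)) {
    check_named_scores(values, "values")
    unknown <- setdiff(names(values), net$nodes)
    if (length(unknown)) {
      abort_invalid(sprintf("value gene(s) not in the network: %s",
                            paste(head(unknown, 5L), collapse = ", ")))
    }
  }
  with_seed(seed, rewire_impl(net, values, swap_fraction))
}

rewire_impl <- function(net, values, swap_fraction) {
  nodes <- net$nodes
  n_nodes <- length(nodes)
  ed <- matrix(match(net$edges, nodes), ncol = 2L)
  m <- nrow(ed)
  target <- ceiling(swap_fraction * m)
  max_tries <- 100L * m

  # per-node value slots; NA marks "no value assigned"
  val <- rep(NA_real_, n_nodes)
  if (!is.null(values)) {
    val[match(names(values), nodes)] <- unname(values)
  }

  exists_edge <- new.env(hash = TRUE, parent = emptyenv(), size = 2L * m)
  ikey <- function(a, b) {
    if (a < b) paste0(a, ".", b) else paste0(b, ".", a)
  }
  for (i in seq_len(m)) {
    assign(ikey(ed[i, 1], ed[i, 2]), TRUE, envir = exists_edge)
  }

  is_original <- rep(TRUE, m)
  n_rewired <- 0L
  n_swaps <- 0L
  tries <- 0L
  while (n_rewired < target && tries < max_tries) {
    tries <- tries + 1L
    e <- sample.int(m, 2L)
    a <- ed[e[1], 1]; b <- ed[e[1], 2]
    c_ <- ed[e[2], 1]; d <- ed[e[2], 2]
    if (runif(1) < 0.5) {      # random orientation of the second edge
      tmp <- c_; c_ <- d; d <- tmp
    }
    if (a == c_ || a == d || b == c_ || b == d) next
    k_ac <- ikey(a, c_)
    k_bd <- ikey(b, d)
    if (exists(k_ac, envir = exists_edge, inherits = FALSE) ||
        exists(k_bd, envir = exists_edge, inherits = FALSE)) next
    rm(list = c(ikey(a, b), ikey(c_, d)), envir = exists_edge)
    assign(k_ac, TRUE, envir = exists_edge)
    assign(k_bd, TRUE, envir = exists_edge)
    ed[e[1], ] <- c(a, c_)
    ed[e[2], ] <- c(b, d)
    for (ei in e) {
      if (is_original[ei]) {
        is_original[ei] <- FALSE
        n_rewired <- n_rewired + 1L
      }
    }
    tmp <- val[b]; val[b] <- val[d]; val[d] <- tmp
    n_swaps <- n_swaps + 1L
  }

  achieved <- n_rewired / m
  converged <- n_rewired >= target
  if (!converged) {
    warn(sprintf(
      "rewiring stopped at %.1f%% of edges after %d attempts (target %.1f%%).",
      100 * achieved, tries, 100 * swap_fraction
    ), class = "tred_warning_partial_rewire")
  }
  new_edges <- matrix(nodes[ed], ncol = 2L)
  keep <- !is.na(val)
  list(
    net = coexpression_network(new_edges, nodes = nodes),
    values = setNames(val[keep], nodes[keep]),
    achieved_fraction = achieved,
    n_swaps = n_swaps,
    converged = converged
  )
}

#' Degree-preserving permutation test for the reversal distance
#'
#' Network-aware analogue of [permutation_test()]: each null draw rewires
#' the coexpression network by degree-preserving double edge swaps,
#' carrying the signature's centered rank-ratio values along with the
#' accumulated node transpositions, and recomputes rd for the relocated
#' signature against the profile.
#'
#' @inheritParams permutation_test
#' @param net A `coexpression_network` whose nodes include the pair's
#'   support genes.
#' @param swap_fraction Proportion of edges to rewire per draw (default 0.8).
#' @return The permutation p-value; with `return_null = TRUE`, null rd
#'   draws attached as attribute `"null_rd"`.
#' @export
network_permutation_test <- function(pair, net, n_perm = 1000, seed = NULL,
                                     sidedness = c("greater", "two_sided"),
                                     swap_fraction = 0.8, return_null = FALSE) {
  sidedness <- match.arg(sidedness)
  if (!inherits(pair, "embedded_pair")) {
    abort_invalid("`pair` must be an embedded_pair.")
  }
  missing <- setdiff(pair$support, net$nodes)
  if (length(missing)) {
    abort_invalid(sprintf("support gene(s) absent from the network: %s",
                          paste(head(missing, 5L), collapse = ", ")))
  }
  obs <- reversal_distance(pair)
  g <- pair$g
  d_full <- pair$d_full
  null_rd <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- rewire_impl(net, g, swap_fraction)
    null_rd_for_assignment(perm$values, d_full)
  }, numeric(1)))
  p <- perm_pvalue(obs, null_rd, sidedness)
  if (return_null) {
    attr(p, "null_rd") <- null_rd
  }
  p
}

# rd of a relocated signature assignment against a profile's full centered
# rank vector; genes that migrated outside the profile are dropped.
null_rd_for_assignment <- function(values, d_full) {
  common <- names(values)[names(values) %in% names(d_full)]
  g <- values[common]
  d <- d_full[common]
  dn <- l2norm(d)
  if (dn == 0 || length(common) < 2L) {
    return(0)
  }
  -sum(g * d) / dn
}
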