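test_that("network constructor rejects self-loops and duplicate edges", {
  expect_error(coexpression_network(rbind(c("a", "a"))),
               class = "tred_error_format")
  expect_error(coexpression_network(rbind(c("a", "b"), c("b", "a"))),
               class = "tred_error_format")
  net <- coexpression_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(unname(degree_sequence(net)), c(2, 2, 2))
})

test_that("double edge swaps preserve the degree sequence exactly", {
  set.seed(431)
  for (i in 1:5) {
    net <- simulate_network(60, mean_degree = 4, seed = 431 + i)
    vals <- setNames(rnorm(20), sprintf("g%05d", 1:20))
    perm <- rewire_preserving_degree(net, vals, swap_fraction = 0.8,
                                     seed = 77 + i)
    expect_identical(degree_sequence(perm$net), degree_sequence(net))
    expect_gte(perm$achieved_fraction, 0.8)
    # values are a permutation of the originals
    expect_equal(sort(unname(perm$values)), sort(unname(vals)))
  }
})

test_that("on a 4-cycle the only valid swap produces the diagonals", {
  # a-b-c-d-a; swapping (a,b) with (c,d) can only create the diagonals
  # a-c / b-d (or a-d / b-c), both preserving degrees (2,2,2,2)
  net <- coexpression_network(rbind(c("a", "b"), c("b", "c"),
                                    c("c", "d"), c("d", "a")))
  # enumerate all candidate swaps by brute force: pairs of disjoint edges
  edges <- net$edges
  diags <- c("a\rc", "b\rd")
  for (e1 in 1:3) for (e2 in (e1 + 1):4) {
    nodes <- c(edges[e1, ], edges[e2, ])
    if (length(unique(nodes)) < 4) next
    # the two possible rewirings of these disjoint edges
    cand1 <- sort(c(paste(sort(nodes[c(1, 3)]), collapse = "\r"),
                    paste(sort(nodes[c(2, 4)]), collapse = "\r")))
    cand2 <- sort(c(paste(sort(nodes[c(1, 4)]), collapse = "\r"),
                    paste(sort(nodes[c(2, 3)]), collapse = "\r")))
    expect_true(identical(cand1, sort(diags)) || identical(cand2, sort(diags)))
  }
  vals <- c(a = 1, b = 2, c = 3, d = 4)
  perm <- rewire_preserving_degree(net, vals, swap_fraction = 0.5, seed = 5)
  expect_identical(unname(degree_sequence(perm$net)), c(2L, 2L, 2L, 2L))
})

test_that("at least the target fraction of original edges is rewired", {
  net <- simulate_network(120, mean_degree = 4, seed = 433)   # ~240 edges
  m <- nrow(net$edges)
  expect_gt(m, 100)
  vals <- setNames(rnorm(length(net$nodes)), net$nodes)
  perm <- rewire_preserving_degree(net, vals, swap_fraction = 0.8, seed = 19)
  expect_true(perm$converged)
  expect_gte(perm$achieved_fraction, 0.8)
  # rewired graph differs from the original
  expect_false(identical(sort(tred:::edge_keys(perm$net$edges)),
                         sort(tred:::edge_keys(net$edges))))
})

test_that("an infeasible rewiring warns and reports the partial fraction", {
  # a triangle admits no valid double edge swap (no two disjoint edges)
  net <- coexpression_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_warning(
    perm <- rewire_preserving_degree(net, c(a = 1, b = 2, c = 3),
                                     swap_fraction = 0.8, seed = 1),
    class = "tred_warning_partial_rewire"
  )
  expect_false(perm$converged)
  expect_equal(perm$achieved_fraction, 0)
})

test_that("network permutation test is deterministic and in range", {
  set.seed(434)
  net <- simulate_network(150, mean_degree = 4, seed = 435)
  prof <- setNames(rnorm(150), net$nodes)
  sig <- setNames(rnorm(30), sample(net$nodes, 30))
  pair <- embed_pair(sig, prof)
  p1 <- network_permutation_test(pair, net, n_perm = 100, seed = 21)
  p2 <- network_permutation_test(pair, net, n_perm = 100, seed = 21)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 101)
  expect_lte(p1, 1)
})

test_that("simulated networks are simple and deterministic", {
  net <- simulate_network(100, mean_degree = 2, seed = 436)
  expect_true(all(net$edges[, 1] != net$edges[, 2]))
  expect_false(anyDuplicated(tred:::edge_keys(net$edges)) > 0)
  # |E| close to n * mean_degree / 2
  expect_gt(nrow(net$edges), 60)
  expect_lt(nrow(net$edges), 140)
  net2 <- simulate_network(100, mean_degree = 2, seed = 436)
  expect_identical(net$edges, net2$edges)
  expect_error(simulate_network(100, mean_degree = 0.5),
               class = "tred_error_invalid_input")
})
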