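test_that("permutation p uses add-one smoothing and is monotone in rd", {
  set.seed(421)
  pair <- random_embedded_pair(n_sig = 25, n_prof = 150)
  # an observed rd far above any achievable null value
  p <- permutation_test(pair, n_perm = 1000, seed = 3, return_null = TRUE)
  null_rd <- attr(p, "null_rd")
  expect_length(null_rd, 1000)
  obs_huge <- max(null_rd) + 1
  expect_equal((1 + sum(null_rd >= obs_huge)) / 1001, 1 / 1001)
  # observed at the null median gives p near 0.5
  p_med <- (1 + sum(null_rd >= median(null_rd))) / 1001
  expect_gt(p_med, 0.4)
  expect_lt(p_med, 0.6)
  # monotone: larger observed rd can only shrink p for a fixed null
  obs_grid <- quantile(null_rd, c(0.1, 0.5, 0.9))
  ps <- vapply(obs_grid, function(o) (1 + sum(null_rd >= o)) / 1001, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("permutation test is deterministic under a fixed seed", {
  set.seed(422)
  pair <- random_embedded_pair()
  p1 <- permutation_test(pair, n_perm = 200, seed = 9)
  p2 <- permutation_test(pair, n_perm = 200, seed = 9)
  expect_identical(p1, p2)
  expect_error(permutation_test(pair, n_perm = 50),
               class = "tred_error_invalid_input")
  expect_no_error(
    permutation_test(pair, n_perm = 200, universe = pair$d_full)
  )
  expect_error(
    permutation_test(pair, n_perm = 200,
                     universe = pair$d_full[seq_len(length(pair$support) - 1)]),
    class = "tred_error_invalid_input"
  )
})

test_that("pooled null p-values agree with per-profile p under exchangeability", {
  set.seed(423)
  pair <- random_embedded_pair(n_sig = 30, n_prof = 200)
  p <- permutation_test(pair, n_perm = 1000, seed = 11, return_null = TRUE)
  null_rd <- attr(p, "null_rd")
  obs <- reversal_distance(pair)
  # pooled computation on the same draws reproduces the smoothed p exactly
  expect_equal(pooled_null_p(obs, null_rd), as.numeric(p))
  # and interpolates consistently on a grid
  qs <- unname(quantile(null_rd, c(0.25, 0.75)))
  expect_equal(pooled_null_p(qs, null_rd),
               vapply(qs, function(o) (1 + sum(null_rd >= o)) / 1001,
                      numeric(1)))
})

test_that("two-SD rule matches direct arithmetic", {
  expect_false(two_sd_flag(10, c(0, 0, 0, 10)))     # mean 2.5, sd 5
  expect_false(two_sd_flag(1, c(1, 1, 1)))          # degenerate sd 0, rd == mean
  expect_true(two_sd_flag(1.0001, c(1, 1, 1)))
  set.seed(424)
  rds <- rnorm(200)
  expect_identical(two_sd_flag(rds, rds), rds > mean(rds) + 2 * sd(rds))
  expect_error(two_sd_flag(1, c(1)), class = "tred_error_invalid_input")
})

test_that("Bonferroni over distinct drugs multiplies and caps", {
  res <- tibble::tibble(
    signature_id = "s1",
    compound = sprintf("d%02d", 1:36),
    rd = rnorm(36),
    p_perm = c(0.001, 0.5, runif(34))
  )
  adj <- adjust_pvalues(res)
  expect_equal(adj$p_adj[1], 0.036)
  expect_equal(adj$p_adj[2], 1)
  # pooled null path: p recomputed against supplied draws, then multiplied
  pool <- list(s1 = seq(-1, 1, length.out = 999))
  adj2 <- adjust_pvalues(res, null_rds = pool)
  expect_equal(adj2$p_pooled,
               vapply(res$rd, function(o) (1 + sum(pool$s1 >= o)) / 1000,
                      numeric(1)))
  expect_equal(adj2$p_adj, pmin(1, adj2$p_pooled * 36))
})

test_that("replicate groups with inconsistent rd direction are removed", {
  res <- tibble::tibble(
    signature_id = "s1",
    replicate_group = c("a", "a", "b", "b", "c"),
    profile_id = sprintf("p%d", 1:5),
    rd = c(1.2, 0.8, 1.2, -0.3, 1.2)
  )
  kept <- filter_replicates(res)
  expect_setequal(kept$profile_id, c("p1", "p2", "p5"))
  expect_identical(kept$unreplicated, c(FALSE, FALSE, TRUE))
})

test_that("confirmatory cell line rule follows sign and significance", {
  base <- tibble::tibble(
    signature_id = "s1",
    compound = "X",
    cell_line = c("A", "B"),
    rd = c(1.2, 0.9),
    nominal_sig = c(TRUE, TRUE),
    unreplicated = c(TRUE, TRUE)
  )
  out <- confirmatory_check(base)
  expect_true(all(out$confirmed))

  only_a <- base[1, ]
  expect_false(confirmatory_check(only_a)$confirmed)

  flipped <- base
  flipped$rd[2] <- -0.4
  expect_false(confirmatory_check(flipped)$confirmed[1])

  not_sig <- base
  not_sig$nominal_sig[2] <- FALSE
  expect_false(confirmatory_check(not_sig)$confirmed[1])
})

test_that("drug prioritization applies the multi-signature and mix rules", {
  mk <- function(compound, sig, kind, p_adj, supported) {
    tibble::tibble(
      signature_id = sig, source_kind = kind, profile_id = paste0(compound, sig),
      compound = compound, rd = 1, p_adj = p_adj,
      nominal_sig = supported, two_sd = supported,
      replicate_consistent = TRUE, unreplicated = FALSE, confirmed = TRUE
    )
  }
  sig_ids <- sprintf("s%d", 1:7)
  kinds <- rep(c("TWAS", "DGE"), length.out = 7)
  # drug A: supported in 4 of 7 signatures, one p_adj = 0.01
  a <- dplyr::bind_rows(lapply(1:7, function(i) {
    mk("A", sig_ids[i], kinds[i], ifelse(i == 1, 0.01, 0.8), i <= 4)
  }))
  # drug B: 2 supported signatures, both TWAS
  b <- dplyr::bind_rows(
    mk("B", "s1", "TWAS", 0.01, TRUE),
    mk("B", "s3", "TWAS", 0.2, TRUE)
  )
  # drug C: 5 supported signatures, no adjusted significance
  c_ <- dplyr::bind_rows(lapply(1:5, function(i) {
    mk("C", sig_ids[i], kinds[i], 0.5, TRUE)
  }))
  res <- dplyr::bind_rows(a, b, c_)

  pri4 <- prioritize_drugs(res, min_signatures = 4)
  expect_true(pri4$passes_threshold[pri4$compound == "A"])
  expect_false(pri4$passes_threshold[pri4$compound == "C"])  # Bonferroni gate

  pri_mix <- prioritize_drugs(res, min_signatures = 2,
                              require_twas_and_dge = TRUE)
  expect_false(pri_mix$passes_threshold[pri_mix$compound == "B"])
  expect_true(pri_mix$passes_threshold[pri_mix$compound == "A"])
})
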