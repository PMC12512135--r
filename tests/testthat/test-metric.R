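test_that("embedding drops unmeasured signature genes and counts them", {
  prof <- setNames(rnorm(26), letters)
  pair <- embed_pair(c(a = 2, b = -1, c = 0.5), prof, min_overlap = 3)
  expect_setequal(pair$support, c("a", "b", "c"))
  expect_equal(pair$n_dropped, 0L)

  pair2 <- embed_pair(c(a = 2, b = -1, q1 = 0.5), prof, min_overlap = 2)
  expect_setequal(pair2$support, c("a", "b"))
  expect_equal(pair2$n_dropped, 1L)

  err <- expect_error(
    embed_pair(setNames(rnorm(5), letters[1:5]), prof, min_overlap = 10),
    class = "tred_error_overlap"
  )
  expect_match(conditionMessage(err), "min_overlap")
})

test_that("drug ranks are global (full profile) before restriction", {
  prof <- setNames(c(10, 9, 1, 2, 3, 4), c("a", "b", "c", "d", "e", "f"))
  pair <- embed_pair(c(a = 1, c = -1), prof, min_overlap = 2)
  # a is top-ranked of 6 genes, c is bottom-ranked
  expect_equal(unname(pair$d[c("a", "c")]), c(1 / 6, 6 / 6) - 0.5)
})

test_that("cosine, rd and d_norm hit the analytic boundary cases", {
  expect_equal(cosine_similarity(c(0.5, -0.5), c(-0.5, 0.5)), -1)
  expect_equal(cosine_similarity(c(0.3, 0.4), c(0.3, 0.4)), 1)
  expect_equal(reversal_distance(c(0.5, -0.5), c(-0.5, 0.5)), sqrt(0.5))
  expect_equal(reversal_distance(c(0.3, 0.4), c(0.3, 0.4)), -0.5)
  expect_equal(reversal_distance(c(1, 0), c(0, 1)), 0)

  gn <- sqrt(0.5)
  expect_equal(normalized_distance(gn, gn), 0)
  expect_equal(normalized_distance(-gn, gn), 2)
  expect_equal(normalized_distance(0, gn), 1)
  expect_error(normalized_distance(2 * gn, gn), class = "tred_error_domain")
})

test_that("omega and rd match an independent computation on random pairs", {
  set.seed(411)
  for (i in 1:50) {
    pair <- random_embedded_pair(n_sig = 50, n_prof = 300)
    om <- oracle_cosine(pair$g, pair$d)
    expect_equal(cosine_similarity(pair), om, tolerance = 1e-12)
    expect_equal(reversal_distance(pair), -sqrt(sum(pair$g^2)) * om,
                 tolerance = 1e-12)
    expect_true(abs(cosine_similarity(pair)) <= 1)
    expect_equal(normalized_distance(pair),
                 (2 / pi) * acos(-om), tolerance = 1e-12)
  }
})

test_that("antisymmetry, convention and scale invariances hold", {
  set.seed(412)
  for (i in 1:25) {
    pair <- random_embedded_pair()
    g <- pair$g
    d <- pair$d
    # negating the drug vector negates omega and rd exactly
    expect_identical(cosine_similarity(g, -d), -cosine_similarity(g, d))
    expect_identical(reversal_distance(g, -d), -reversal_distance(g, d))
    # negating both centered vectors leaves rd unchanged
    expect_equal(reversal_distance(-g, -d), reversal_distance(g, d),
                 tolerance = 1e-12)
    # rd invariant to positive rescaling of d, linear in ||g||
    expect_equal(reversal_distance(g, 3.7 * d), reversal_distance(g, d),
                 tolerance = 1e-12)
    expect_equal(reversal_distance(2.5 * g, d), 2.5 * reversal_distance(g, d),
                 tolerance = 1e-12)
  }
})

test_that("sensitivity derivatives match the closed forms and their limits", {
  set.seed(413)
  pair <- random_embedded_pair(n_sig = 20, n_prof = 100)
  sens <- sensitivity(pair)
  for (i in seq(1, 20, by = 3)) {
    expect_equal(sens$domega_dd[i], fd_domega(pair$g, pair$d, i, "d"),
                 tolerance = 1e-6)
    expect_equal(sens$domega_dg[i], fd_domega(pair$g, pair$d, i, "g"),
                 tolerance = 1e-6)
  }

  # orthogonal pair: second term vanishes
  g <- c(a = 1, b = 0, c = -1, d = 0)
  d <- c(a = 0, b = 1, c = 0, d = 1)
  s <- sum(g * d)
  expect_equal(s, 0)
  pair_ortho <- structure(
    list(signature_id = "s", profile_id = "p", support = names(g),
         g = g, d = d, d_full = d, n_dropped = 0L,
         g_norm = sqrt(sum(g^2)), d_norm = sqrt(sum(d^2))),
    class = "embedded_pair"
  )
  so <- sensitivity(pair_ortho)
  expect_equal(so$domega_dd, unname(g / (sqrt(2) * sqrt(2))))

  # d = g: omega at its maximum, all derivatives vanish
  pair_eq <- pair_ortho
  pair_eq$d <- g
  pair_eq$d_norm <- pair_eq$g_norm
  se <- sensitivity(pair_eq)
  expect_equal(se$domega_dd, rep(0, 4))

  expect_error(sensitivity(pair, genes = "nope"), class = "tred_error_key")
})

test_that("delta moments: gradient, degenerate covariance, PSD check", {
  dm0 <- delta_moments(c(0.3, 2, 3), matrix(0, 3, 3))
  expect_equal(dm0$var_approx, 0)
  expect_equal(dm0$mean_approx, 0.3 / sqrt(6))

  dm <- delta_moments(c(0, 1, 1), diag(3))
  expect_equal(dm$gradient, c(1, 0, 0))
  expect_equal(dm$var_approx, 1)

  bad <- diag(c(1, 1, -1))
  expect_error(delta_moments(c(0, 1, 1), bad),
               class = "tred_error_invalid_input")
  expect_error(delta_moments(c(0, -1, 1), diag(3)),
               class = "tred_error_invalid_input")

  expect_named(glance(dm), c("mean_approx", "var_approx"))
})

test_that("softmax is stable, normalized and shift-invariant", {
  expect_equal(softmax_prioritize(c(0, 0)), c(0.5, 0.5))
  p <- softmax_prioritize(c(1, 0))
  expect_equal(p, c(exp(1), 1) / (exp(1) + 1))
  big <- softmax_prioritize(c(1000, 999))
  expect_true(all(is.finite(big)))
  expect_equal(big, p, tolerance = 1e-12)
  set.seed(414)
  x <- rnorm(20)
  expect_equal(sum(softmax_prioritize(x)), 1, tolerance = 1e-12)
  expect_equal(softmax_prioritize(x + 57.3), softmax_prioritize(x),
               tolerance = 1e-12)
  expect_error(softmax_prioritize(numeric()), class = "tred_error_invalid_input")
})

test_that("argmax_drug is deterministic with lexicographic tie-break", {
  expect_equal(argmax_drug(c(A = 1.2, B = 0.3)), "A")
  expect_equal(argmax_drug(c(B = 1.2, A = 1.2)), "A")
  set.seed(415)
  rds <- setNames(rnorm(1000), sprintf("p%04d", sample(1000)))
  expect_equal(argmax_drug(rds), names(rds)[which.max(rds)])
  expect_error(argmax_drug(setNames(numeric(), character())),
               class = "tred_error_invalid_input")
})
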