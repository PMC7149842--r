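# Statistics kernel: Pearson chi-square, Fisher exact, pooled t.

test_that("pearson_chi2 reproduces the six published carrier tables", {
  # (a, c, printed p) at n = 37 cases / 534 controls
  cases <- list(
    list(a = 3, c = 1, printed = 0.00000002, digits = 1),
    list(a = 3, c = 5, printed = 0.0003, digits = 1),
    list(a = 2, c = 2, printed = 0.0004, digits = 1),
    list(a = 2, c = 4, printed = 0.0072, digits = 2),
    list(a = 3, c = 11, printed = 0.0214, digits = 3)
  )
  for (cs in cases) {
    p <- pearson_chi2(two_by_two(cs$a, 37 - cs$a, cs$c, 534 - cs$c))$p
    expect_equal(signif(p, cs$digits), cs$printed,
                 info = sprintf("a=%d c=%d", cs$a, cs$c))
  }
  p_olig <- pearson_chi2(two_by_two(7, 30, 30, 504))$p
  expect_equal(signif(p_olig, 3), 0.00148)
})

test_that("pearson_chi2 matches stats::chisq.test and handles degeneracy", {
  set.seed(42)
  for (i in 1:25) {
    a <- rpois(1, 3); b <- rpois(1, 20) + 1
    cc <- rpois(1, 5); d <- rpois(1, 200) + 1
    ours <- pearson_chi2(two_by_two(a, b, cc, d))
    ref <- suppressWarnings(
      stats::chisq.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                        correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    # invariance under simultaneous row and column transposition
    swapped <- pearson_chi2(two_by_two(d, cc, b, a))
    expect_equal(swapped$statistic, ours$statistic, tolerance = 1e-12)
  }
  expect_equal(pearson_chi2(two_by_two(0, 10, 0, 20)), list(statistic = 0, p = 1))
  expect_equal(pearson_chi2(two_by_two(1, 9, 1, 9))$statistic, 0)
  expect_error(pearson_chi2(two_by_two(0, 0, 1, 9)), "degenerate")
})

test_that("fisher_exact matches the enumeration oracle on sampled tables", {
  expect_equal(fisher_exact(two_by_two(3, 34, 1, 533), "one_sided_enrichment"),
               9.617461e-04, tolerance = 1e-06)
  expect_equal(fisher_exact(two_by_two(0, 37, 0, 534), "one_sided_enrichment"), 1)
  expect_equal(fisher_exact(two_by_two(0, 37, 0, 534), "two_sided"), 1)
  # one-sided enrichment for the oligogenic table, checked against the
  # enumeration oracle
  expect_equal(fisher_exact(two_by_two(7, 30, 30, 504), "one_sided_enrichment"),
               oracle_fisher(7, 30, 30, 504, "one_sided_enrichment"),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:60) {
    n <- sample(4:40, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    cc <- sample(0:(n - a - b), 1); d <- n - a - b - cc
    if (a + b == 0 || cc + d == 0) next
    tb <- two_by_two(a, b, cc, d)
    for (alt in c("one_sided_enrichment", "two_sided")) {
      ours <- fisher_exact(tb, alt)
      ref <- oracle_fisher(a, b, cc, d, alt)
      expect_equal(ours, ref, tolerance = 1e-10,
                   info = sprintf("%d,%d,%d,%d %s", a, b, cc, d, alt))
    }
    # cross-check the two-sided value against stats::fisher.test as a third
    # independent route
    expect_equal(fisher_exact(tb, "two_sided"),
                 stats::fisher.test(matrix(c(a, b, cc, d), 2,
                                           byrow = TRUE))$p.value,
                 tolerance = 1e-08)
  }
})

test_that("one-sided Fisher p decreases in a at fixed margins, bounded by two-sided", {
  n_case <- 37; n_ctrl <- 534
  n <- n_case + n_ctrl
  for (k in c(1, 4, 12, 37)) {
    # p1 <= p2 holds from the pmf mode upward (the enrichment side, the
    # only side the scan interprets); below the mode P(X >= a) approaches 1
    # while the two-sided sum can be small, so no bound is asserted there
    mode_a <- floor((k + 1) * (n_case + 1) / (n + 2))
    prev <- Inf
    for (a in max(0, k - n_ctrl):min(k, n_case)) {
      tb <- two_by_two(a, n_case - a, k - a, n_ctrl - (k - a))
      p1 <- fisher_exact(tb, "one_sided_enrichment")
      p2 <- fisher_exact(tb, "two_sided")
      expect_lte(p1, prev + 1e-12)
      expect_lte(p1, 1)
      if (a >= mode_a) expect_lte(p1, p2 + 1e-12)
      prev <- p1
    }
  }
})

test_that("mean_burden_t_test matches the frozen pooled-variance oracle", {
  res <- mean_burden_t_test(c(2, 4), c(1, 3, 2))
  expect_equal(res$t, 3 / sqrt(10), tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p_one_tailed, 0.2063852, tolerance = 1e-06)
  # cross-check against stats::t.test on random draws
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(6, 1); y <- rnorm(9)
    ref <- stats::t.test(x, y, var.equal = TRUE, alternative = "greater")
    ours <- mean_burden_t_test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_one_tailed, ref$p.value, tolerance = 1e-10)
  }
})

test_that("mean_burden_t_test degenerate conventions", {
  expect_equal(mean_burden_t_test(c(2, 2), c(2, 2, 2))$p_one_tailed, 0.5)
  expect_equal(mean_burden_t_test(c(3, 3), c(1, 1))$p_one_tailed, 0)
  expect_equal(mean_burden_t_test(c(1, 1), c(3, 3))$p_one_tailed, 1)
  # separation with tiny jitter: direction check
  p <- mean_burden_t_test(c(3, 3, 3, 3) + 1e-09 * (1:4),
                          c(1, 1, 1, 1) + 1e-09 * (1:4))$p_one_tailed
  expect_lt(p, 1e-04)
  expect_error(mean_burden_t_test(1, c(1, 2)), "at least 2")
})

test_that("two_by_two rejects invalid cells", {
  expect_error(two_by_two(-1, 2, 3, 4), "non-negative")
  expect_error(two_by_two(1.5, 2, 3, 4), "non-negative integers")
})
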