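test_that("Welch t test handles degenerate and separated groups", {
  r <- welch_t_one_sided(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3), "greater")
  expect_equal(r$statistic, 0)
  expect_equal(r$pvalue, 0.5)

  r <- welch_t_one_sided(c(0.9, 0.8, 0.85, 0.95), c(0.1, 0.2, 0.15, 0.05),
                         "greater")
  expect_lt(r$pvalue, 0.01)
  # same data, wrong direction: non-significant
  r2 <- welch_t_one_sided(c(0.9, 0.8, 0.85, 0.95), c(0.1, 0.2, 0.15, 0.05),
                          "less")
  expect_gt(r2$pvalue, 0.99)

  # insufficient data flagged, not an error
  expect_true(is.na(welch_t_one_sided(1, c(1, 2), "greater")$pvalue))
})

test_that("Welch p matches a numerically integrated t density", {
  x <- c(0.82, 0.74, 0.91, 0.66, 0.88, 0.79)
  y <- c(0.41, 0.52, 0.47, 0.39, 0.58, 0.44)
  # independent arithmetic for the statistic and df
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  dens <- function(z) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + z^2 / df)^(-(df + 1) / 2)
  }
  oracle <- integrate(dens, tstat, Inf, rel.tol = 1e-12)$value
  got <- welch_t_one_sided(x, y, "greater")
  expect_equal(got$statistic, tstat, tolerance = 1e-12)
  expect_equal(got$pvalue, oracle, tolerance = 1e-10)
})

test_that("Mann-Whitney is exact in the small tie-free regime", {
  r <- mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$pvalue, 1 / 20)
  expect_true(r$exact)

  x <- c(1, 2, 3)
  expect_gte(mann_whitney_one_sided(x, x, "greater")$pvalue, 0.5)
  expect_equal(mann_whitney_one_sided(c(2, 2), c(2, 2, 2), "greater")$pvalue, 1)
})

test_that("Mann-Whitney p equals rank enumeration for tie-free n1+n2 <= 10", {
  set.seed(101)
  for (i in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    for (alt in c("greater", "less")) {
      expect_equal(mann_whitney_one_sided(x, y, alt)$pvalue,
                   mw_enum_p(x, y, alt), tolerance = 1e-12,
                   info = sprintf("case %d alt %s", i, alt))
    }
  }
})

test_that("Fisher enrichment: odds ratio, CI and exact p", {
  r <- fisher_exact_enrichment(5, 5, 50, 50)
  expect_equal(r$odds_ratio, 1)
  expect_gt(r$pvalue, 0.5)

  r <- fisher_exact_enrichment(8, 2, 10, 80)
  expect_equal(r$odds_ratio, 32)
  expect_equal(r$pvalue, fisher_enum_p(8, 2, 10, 80), tolerance = 1e-12)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)

  # feature absent everywhere: corrected OR finite, CI spans 1, p = 1
  r <- fisher_exact_enrichment(0, 10, 0, 90)
  expect_true(is.finite(r$odds_ratio))
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
  expect_equal(r$pvalue, 1)

  expect_error(fisher_exact_enrichment(0, 0, 0, 0), "all-zero")
})

test_that("Fisher one-sided p equals the enumeration oracle on random tables", {
  set.seed(7)
  for (i in 1:50) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    cc <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b + cc + d == 0) next
    expect_equal(fisher_exact_enrichment(a, b, cc, d)$pvalue,
                 fisher_enum_p(a, b, cc, d), tolerance = 1e-12,
                 info = sprintf("table %d %d %d %d", a, b, cc, d))
  }
})

test_that("BH adjustment follows the step-up formula and its properties", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))

  set.seed(3)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p) && all(q <= 1))
  # constant vectors are fixed points; adjustment is permutation-equivariant
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), q[perm])
  # order preservation: sorting by p sorts by padj
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("empirical p-value uses the add-one convention", {
  expect_equal(empirical_p(0.0001, seq(0.001, 0.999, length.out = 999)), 1 / 1000)
  expect_equal(empirical_p(2, runif(50)), 1)
  expect_equal(empirical_p(0.5, c(rep(0.5, 4), seq(0.6, 1, length.out = 95))),
               5 / 100)
  expect_gt(empirical_p(-Inf, rnorm(10)), 0)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("batch rank scorer agrees with the full Mann-Whitney approximation", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(12)
    got <- methlink:::mw_batch_p(matrix(x, 1), matrix(y, 1), "greater")
    ref <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                        exact = FALSE, correct = TRUE))$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})
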