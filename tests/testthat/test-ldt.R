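test_that("cross-product blocks equal centered sums of products", {
  x1 <- matrix(c(1, 2, 3), 1)
  x2 <- matrix(c(2, 4, 6), 1)
  b <- ldt_cross_products(x1, x2)
  expect_equal(b$A11[1, 1], 2)    # (-1,0,1) sum of squares
  expect_equal(b$A12[1, 1], 4)
  expect_equal(b$A22[1, 1], 8)
  expect_equal(b$A21, t(b$A12))

  # against the textbook unbiased covariance (independent oracle)
  set.seed(3)
  x <- matrix(rnorm(4 * 30), 4, 30)
  y <- matrix(rnorm(4 * 30), 4, 30)
  b <- ldt_cross_products(x, y)
  expect_equal(b$A11 / 29, cov(t(x)), tolerance = 1e-12)
  expect_equal(b$A12 / 29, cov(t(x), t(y)), tolerance = 1e-12)
  expect_true(isSymmetric(b$A11) && isSymmetric(b$A22))

  expect_error(ldt_cross_products(matrix(0, 2, 5), matrix(0, 2, 6)),
               "sample-axis mismatch")
  expect_error(ldt_cross_products(matrix(0, 1, 1), matrix(0, 1, 1)),
               "2 samples")
})

test_that("the trace statistic sums squared sample canonical correlations", {
  set.seed(10)
  # identical full-rank blocks: every canonical correlation is 1
  x <- matrix(rnorm(4 * 20), 4, 20)
  expect_equal(ldt_statistic(x, x + 0), 4, tolerance = 1e-8)
  # perfectly correlated single exons
  expect_equal(ldt_statistic(matrix(c(1, 2, 3), 1), matrix(c(2, 4, 6), 1)),
               1, tolerance = 1e-12)
  # canonical-correlation oracle on a larger random instance
  x <- matrix(rnorm(5 * 40), 5, 40)
  y <- matrix(rnorm(3 * 40), 3, 40)
  cc <- cancor(t(x), t(y))
  expect_equal(ldt_statistic(x, y), sum(cc$cor^2), tolerance = 1e-8)
  # degenerate blocks are refused with actionable advice
  zero_var <- rbind(x, 0)
  expect_error(ldt_statistic(zero_var, y), "zero-variance")
})

test_that("asymptotic moments follow the stated closed form", {
  m <- ldt_moments(5, 5, 51)
  expect_equal(m$E, 0.5)
  expect_equal(m$V, 0.0162)
  m <- ldt_moments(1, 1, 101)
  expect_equal(m$E, 0.01)
  expect_equal(m$V, 1.9602e-4)
  # boundary of the supported regime: n - 1 - p = 0
  expect_error(ldt_moments(5, 5, 6), "n - 1 > max")
  expect_error(ldt_moments(0, 5, 100), ">= 1")
})

test_that("the standardized statistic centers and scales the trace", {
  set.seed(21)
  x <- matrix(rnorm(3 * 30), 3, 30)
  y <- matrix(rnorm(3 * 30), 3, 30)
  res <- ldt_test(x, y)
  mom <- ldt_moments(3, 3, 30)
  expect_equal(res$E, mom$E)
  expect_equal(res$V, mom$V)
  expect_equal(res$statistic[["T"]],
               (res$estimate[["L_n"]] - mom$E) / sqrt(mom$V))
  expect_equal(res$p.value, pnorm(res$statistic[["T"]], lower.tail = FALSE))
})

test_that("under the null T is approximately standard normal", {
  set.seed(6)
  p <- 5; n <- 100
  mom <- ldt_moments(p, p, n)
  t_vals <- replicate(4000, {
    pair <- simulate_pair(p, p, n, dependent = FALSE)
    (ldt_statistic(pair$x, pair$y) - mom$E) / sqrt(mom$V)
  })
  expect_lt(abs(mean(t_vals)), 0.1)
  expect_gt(var(t_vals), 0.8)
  expect_lt(var(t_vals), 1.2)
})

test_that("the edge decision compares T to the upper alpha quantile", {
  set.seed(2)
  dep <- simulate_pair(5, 5, 100, c0 = 0.8)
  res <- ldt_test(dep$x, dep$y, alpha = 0.05)
  expect_true(res$statistic[["T"]] > qnorm(0.95))
  expect_true(res$edge)
  expect_true(res$p.value < 0.05)

  ind <- simulate_pair(5, 5, 100, dependent = FALSE)
  res0 <- ldt_test(ind$x, ind$y, alpha = 1e-6)
  expect_false(res0$edge)
  expect_equal(res0$critical.value, qnorm(1 - 1e-6))

  # edge decision and p-value threshold agree
  expect_equal(res0$edge, res0$p.value < res0$alpha)
})

test_that("zero-variance exons are removed with updated dimensions", {
  set.seed(4)
  x <- rbind(matrix(rnorm(3 * 30), 3, 30), 7)   # constant fourth exon
  y <- matrix(rnorm(2 * 30), 2, 30)
  expect_warning(res <- ldt_test(x, y), "zero-variance")
  expect_equal(unname(res$parameter[["p"]]), 3)
  # the unsupported regime is refused, advising exon filtering
  expect_error(suppressWarnings(ldt_test(matrix(rnorm(10 * 8), 10, 8),
                                         matrix(rnorm(2 * 8), 2, 8))),
               "filter")
})

test_that("the statistic is bounded, affine-invariant and symmetric", {
  set.seed(77)
  for (rep in 1:40) {
    p <- sample(1:8, 1)
    q <- sample(1:8, 1)
    n <- sample((p + q + 2):50, 1)
    x <- matrix(rnorm(p * n), p, n)
    y <- matrix(rnorm(q * n), q, n)
    L <- ldt_statistic(x, y)
    expect_gte(L, 0)
    expect_lte(L, min(p, q) + 1e-10)
    # block swap leaves everything unchanged
    expect_equal(ldt_statistic(y, x), L, tolerance = 1e-10)
    m1 <- ldt_moments(p, q, n)
    m2 <- ldt_moments(q, p, n)
    expect_equal(m1$E, m2$E)
    expect_equal(m1$V, m2$V)
    # invariance under per-block invertible affine maps
    b1 <- matrix(rnorm(p * p), p) + diag(p)
    b2 <- matrix(rnorm(q * q), q) + diag(q)
    L2 <- ldt_statistic(b1 %*% x + rnorm(p), b2 %*% y + rnorm(q))
    expect_equal(L2, L, tolerance = 1e-8)
  }
})
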