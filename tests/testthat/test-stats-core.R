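test_that("pearson_r recovers hand-computed correlations", {
  x <- 1:5
  r1 <- pearson_r(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  # hand covariance/variance computation: r = 3 / sqrt(5 * 5) = 0.6
  r3 <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r3$r, 0.6)
  expect_true(r3$ci_low <= r3$r && r3$r <= r3$ci_high)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:4, 1:3), "unequal")
})

test_that("fisher_ci reproduces the published intervals and is antisymmetric", {
  expect_equal(fisher_ci(-0.243, 532), c(-0.321, -0.161))
  expect_equal(fisher_ci(-0.500, 18), c(-0.784, -0.043))
  # symmetric about 0 at r = 0
  ci0 <- fisher_ci(0, 50)
  expect_equal(ci0[1], -ci0[2])
  # antisymmetry: ci(-r, n) = -rev(ci(r, n))
  for (r in c(0.1, 0.45, 0.9)) for (n in c(10, 100, 500))
    expect_equal(fisher_ci(-r, n), -rev(fisher_ci(r, n)))
  expect_error(fisher_ci(1, 100), "undefined")
  expect_error(fisher_ci(0.5, 3), "n >= 4")
})

test_that("independent t matches pooled hand computation and reports F = t^2", {
  # sp^2 = 1, se = sqrt(2/3) = 0.8165, t = -3 / 0.8165
  tt <- independent_t(c(1, 2, 3), c(4, 5, 6), equal_var = TRUE)
  expect_equal(tt$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(tt$f, tt$statistic^2, tolerance = 1e-9)
  # identical groups: t = 0, p = 1
  t0 <- independent_t(c(2, 2), c(2, 2))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  same <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(independent_t(1, c(1, 2)), "n >= 2")
})

test_that("chi-square independence matches the 2x2 closed form and brute-force expected counts", {
  # n (ad - bc)^2 / (r1 r2 c1 c2) = 60 * 90000 / 810000
  res <- chi_square_independence(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(res$statistic, 6.666667, tolerance = 1e-6)
  expect_equal(res$df, 1)
  # proportional columns: X^2 = 0
  expect_equal(chi_square_independence(matrix(c(10, 20, 20, 40), 2))$statistic, 0)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2)),
               "zero row or column")
  # brute-force (O - E)^2 / E oracle over random small tables
  set.seed(33)
  for (i in 1:50) {
    tab <- matrix(sample(1:20, 4, replace = TRUE), 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_independence(tab)$statistic,
                 sum((tab - e)^2 / e), tolerance = 1e-9)
  }
})

test_that("two-proportion z uses the pooled SE and is symmetric in its groups", {
  z <- two_proportion_z(113, 1721, 386, 1490)
  expect_equal(round(z$z, 3), 15.086)
  zs <- two_proportion_z(386, 1490, 113, 1721)
  expect_equal(z$z, zs$z)
  expect_equal(z$p, zs$p)
  # equal proportions: z = 0, p = 1
  z0 <- two_proportion_z(5, 10, 10, 20)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  expect_error(two_proportion_z(0, 10, 0, 20), "pooled proportion")
  expect_error(two_proportion_z(11, 10, 1, 20), "0 <= k <= n")
})

test_that("BH adjustment is step-up, order invariant and idempotent on flat inputs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  set.seed(34)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
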