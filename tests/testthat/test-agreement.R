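test_that("Bland-Altman reduces correctly on identical methods and is antisymmetric", {
  x <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  expect_equal(ba$n_outside, 0)
  expect_true(ba$loa_collapsed)

  set.seed(1)
  y <- x + rnorm(5)
  expect_equal(bland_altman(x, y)$bias, -bland_altman(y, x)$bias)
})

test_that("Bland-Altman matches hand arithmetic on a 10-point set", {
  x <- c(150, 180, 200, 170, 160, 210, 190, 175, 165, 185)
  y <- c(145, 190, 195, 180, 150, 220, 185, 170, 175, 180)
  ba <- bland_altman(x, y)
  d <- x - y
  m <- sum(d) / 10
  s <- sqrt(sum((d - m)^2) / 9)
  expect_equal(ba$bias, m)
  expect_equal(ba$loa_low, m - 1.96 * s)
  expect_equal(ba$loa_high, m + 1.96 * s)
  expect_equal(ba$bias_ci, m + c(-1, 1) * qt(0.975, 9) * s / sqrt(10))
  expect_equal(ba$n_outside, sum(d < ba$loa_low | d > ba$loa_high))
})

test_that("about 5% of Gaussian differences fall outside the 1.96 limits", {
  set.seed(2)
  n <- 1e4
  x <- rnorm(n, 100, 10)
  y <- x + rnorm(n, 0, 5)
  ba <- bland_altman(x, y)
  expect_gt(ba$n_outside / n, 0.04)
  expect_lt(ba$n_outside / n, 0.06)
})

test_that("Passing-Bablok recovers the identity line and is equivariant", {
  x <- c(1, 2, 3, 5, 8, 13)
  pb <- passing_bablok(x, x)
  expect_equal(pb$slope, 1)
  expect_equal(pb$intercept, 0)

  set.seed(3)
  y <- 2 * x + rnorm(6, 0, 0.1)
  for (c_scale in c(0.5, 3)) {
    expect_equal(passing_bablok(x, c_scale * y)$slope,
                 c_scale * passing_bablok(x, y)$slope)
  }
  # axis swap inverts the slope when all pairwise slopes are positive;
  # with 6 points the 15 slopes have an odd count, so the shifted median
  # maps exactly to its reciprocal under the swap
  pb_xy <- passing_bablok(x, y)
  pb_yx <- passing_bablok(y, x)
  expect_equal(pb_yx$slope, 1 / pb_xy$slope, tolerance = 1e-12)
})

test_that("Passing-Bablok slope matches exhaustive enumeration on small sets", {
  sets <- list(
    list(x = c(1, 2, 3, 4, 5), y = c(1.1, 2.3, 2.8, 4.2, 5.1)),
    list(x = c(10, 12, 15, 18, 20, 25), y = c(21, 26, 29, 38, 39, 52)),
    list(x = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
         y = c(2, 1, 4, 3, 7, 6, 8, 10, 9, 12)))
  for (s in sets) {
    pb <- passing_bablok(s$x, s$y)
    expect_equal(pb$slope, brute_pb_slope(s$x, s$y))
    expect_true(pb$slope_ci[1] <= pb$slope && pb$slope <= pb$slope_ci[2])
    expect_equal(pb$intercept, median(s$y - pb$slope * s$x))
  }
  # tied x values are skipped and counted
  xt <- c(1, 1, 2, 3, 4)
  pbt <- passing_bablok(xt, c(1, 1.2, 2, 3, 4))
  expect_equal(pbt$n_tied_x_skipped, 1)
  expect_error(passing_bablok(c(1, 1, 1, 2), c(1, 2, 3, 4)),
               "distinct x")
})

test_that("Passing-Bablok is consistent for a proportional bias", {
  set.seed(4)
  n <- 500
  x <- runif(n, 50, 350)
  b <- 1.3
  y <- b * x + rnorm(n, 0, 15)
  pb <- passing_bablok(x, y)
  expect_equal(pb$slope, b, tolerance = 0.05)
})

test_that("least-squares line matches the normal equations", {
  x <- c(1, 2, 4, 7)
  y <- c(2.1, 3.9, 8.2, 13.8)
  ls <- least_squares_line(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(ls$intercept, beta[1])
  expect_equal(ls$slope, beta[2])
  expect_equal(least_squares_line(x, 2 * x + 3)$r_squared, 1)
  expect_equal(least_squares_line(x, x + 5)$slope, 1)
  expect_error(least_squares_line(rep(2, 4), y), "zero variance")
})

test_that("paired t-test matches manual computation and conventions", {
  x <- c(12, 15, 11, 14, 13)
  y <- c(10, 14, 12, 11, 12)
  tt <- paired_t(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(tt$t, t_manual)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * pt(-abs(t_manual), 4))
  # identical vectors: t = 0, p = 1 by convention
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # sign flip
  expect_equal(paired_t(y, x)$t, -tt$t)
})

test_that("method pairing aligns ejaculates and honours the replicate policy", {
  sim <- generate_dataset(paper_like_config(seed = 23))
  pr <- pair_methods(sim$records, "Accuread", "ISASv1")
  expect_equal(length(pr$x), 50)  # 10 boars x 5 ejaculates, replicate means
  pr_keep <- pair_methods(sim$records, "Accuread", "ISASv1",
                          policy = "keep")
  expect_equal(length(pr_keep$x), 100)
  # paired values come from the same ejaculate
  rec <- aggregate_replicates(sim$records, "mean")
  i <- match(pr$ejaculate_id, rec$ejaculate_id[rec$method == "Accuread"])
  expect_equal(pr$x, rec$concentration[rec$method == "Accuread"][i])
})
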