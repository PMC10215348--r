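test_that("contrast reconstruction matches hand-computed level differences", {
  # 5-draw toy chain over 3 levels with sum-to-zero coding
  B <- matrix(c(1, 2, 0, -1, 3,
                0, 1, 2, 1, -2), ncol = 2)
  ch <- make_toy_chains(B, c("a", "b", "c"), intercept = 10)
  eff_a <- B[, 1]
  eff_b <- B[, 2]
  eff_c <- -(eff_a + eff_b)
  expect_equal(contrast_samples(ch, "method", "a", "b"), eff_a - eff_b)
  expect_equal(contrast_samples(ch, "method", "a", "c"), eff_a - eff_c)
  expect_equal(level_mean_samples(ch, "method", "c"), 10 + eff_c)
  # self-contrast and antisymmetry
  expect_equal(contrast_samples(ch, "method", "b", "b"), rep(0, 5))
  expect_equal(contrast_samples(ch, "method", "a", "c"),
               -contrast_samples(ch, "method", "c", "a"))
  expect_error(contrast_samples(ch, "method", "a", "zz"), "unknown level")
})

test_that("hpd finds the shortest window", {
  expect_equal(hpd(1:100, 0.95), c(1, 95))
  # brute-force shortest-window oracle on assorted shapes
  set.seed(42)
  for (x in list(rnorm(500), rexp(500), c(rnorm(250), rnorm(250, 6)),
                 runif(500))) {
    for (lev in c(0.5, 0.8, 0.95)) {
      expect_equal(hpd(x, lev), brute_hpd(x, lev))
    }
  }
  # standard normal quantiles at large n
  set.seed(1)
  z <- rnorm(1e5)
  h <- hpd(z, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.05 / 1.96)
  expect_equal(h[2], 1.96, tolerance = 0.05 / 1.96)
  # width is non-decreasing in level; level -> 1 spans the range
  widths <- vapply(c(0.5, 0.7, 0.9, 0.95, 0.99), function(l)
    diff(hpd(z, l)), 0)
  expect_true(all(diff(widths) >= 0))
  expect_equal(hpd(z, 0.999999), range(z))
  expect_error(hpd(rnorm(50), 0.95), "too few")
})

test_that("p0 takes the posterior-mean side and matches the normal oracle", {
  expect_equal(p0(c(0.5, 1, 2)), 1)
  expect_equal(p0(c(-1, 1)), 0.5)  # mean exactly zero
  set.seed(2)
  for (pars in list(c(1, 2), c(-0.5, 1), c(3, 10))) {
    x <- rnorm(2e5, pars[1], pars[2])
    expect_equal(p0(x), pnorm(abs(pars[1]) / pars[2]), tolerance = 0.01)
  }
})

test_that("relevance partition is exact and matches normal tails", {
  expect_equal(relevance_partition(c(-0.5, 0.1, 0.4), R = 1),
               c(PR = 0, PS = 1, opposite = 0))
  set.seed(3)
  # dyadic sample sizes make count/n exact, so the identity is bit-exact
  for (n in c(64, 256, 1024)) {
    for (i in 1:10) {
      x <- rnorm(n, runif(1, -3, 3), runif(1, 0.5, 2))
      part <- relevance_partition(x, R = runif(1, 0.1, 2))
      expect_identical(sum(part), 1)
    }
  }
  part <- relevance_partition(rnorm(199), R = 0.5)
  expect_equal(sum(part), 1, tolerance = 1e-12)
  x <- rnorm(5e5, 1, 1.5)
  expect_equal(relevance_prob(x, 2), pnorm((1 - 2) / 1.5), tolerance = 0.01)
  expect_equal(similitude_prob(x, 2),
               pnorm((2 - 1) / 1.5) - pnorm((-2 - 1) / 1.5),
               tolerance = 0.01)
})

test_that("guaranteed value follows the sign convention and is monotone in k", {
  # positive mean: (1-k) quantile; negative mean: k quantile
  g <- gaussian_grid(1e6, 186.2, (211.1 - 160.8) / (2 * qnorm(0.975)))
  expect_equal(guaranteed_value(g, 0.80), 175.4, tolerance = 0.2 / 175.4)
  gn <- gaussian_grid(1e6, -19.7, (3.0 - (-41.8)) / (2 * qnorm(0.975)))
  expect_equal(guaranteed_value(gn, 0.80), -10.1, tolerance = 0.2 / 10.1)
  x <- rnorm(1e4, 5, 2)
  expect_equal(guaranteed_value(x, 0.5), median(x))
  ks <- seq(0.1, 0.9, 0.1)
  expect_true(all(diff(vapply(ks, function(k)
    guaranteed_value(x, k), 0)) <= 0))
  xn <- -x
  expect_true(all(diff(vapply(ks, function(k)
    guaranteed_value(xn, k), 0)) >= 0))
})

test_that("Geweke Z is calibrated on iid chains and detects trends", {
  set.seed(4)
  zs <- replicate(500, geweke_z(rnorm(1000)))
  frac <- mean(abs(zs) > 1.96)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.10)
  # linear trend of 5 sd over the chain
  set.seed(5)
  drift <- rnorm(1000) + seq(0, 5, length.out = 1000)
  expect_gt(abs(geweke_z(drift)), 3)
  # identical first-10% and last-50% windows give exactly zero
  a <- rnorm(100)
  x <- c(a, rnorm(400), rep(a, 5))
  expect_equal(geweke_z(x), 0)
  expect_error(geweke_z(rnorm(50)), "too short")
})

test_that("batch-means MCSE scales as sigma/sqrt(n) and grows with autocorrelation", {
  set.seed(6)
  x <- rnorm(1e4)
  expect_equal(mcse(x), 1 / sqrt(1e4), tolerance = 0.25)
  # AR(1), phi = 0.9: asymptotic sd of the mean inflated by sqrt(19)
  ar1 <- as.numeric(arima.sim(list(ar = 0.9), 1e4))
  expect_gt(mcse(ar1), 2 * mcse(x))
  expect_equal(mcse(rep(3, 1000)), 0)
})

test_that("level summaries reduce correctly in the degenerate case", {
  B <- matrix(rep(c(2, -1), each = 50), ncol = 2)  # constant draws
  ch <- make_toy_chains(B, c("a", "b", "c"), intercept = 7)
  row <- summarize_level(ch, "method", "a")
  expect_equal(row$mean, 9)
  expect_equal(c(row$hpd_low, row$hpd_high), c(9, 9))
  expect_equal(row$gvk, 9)
  # guaranteed value of level-mean samples consistent with a sort oracle
  set.seed(7)
  B2 <- cbind(rnorm(400), rnorm(400))
  ch2 <- make_toy_chains(B2, c("a", "b", "c"), intercept = 130)
  s <- level_mean_samples(ch2, "method", "b")
  expect_equal(guaranteed_value(s, 0.8),
               unname(quantile(s, 0.2)))
})

test_that("contrast summary row assembles all published-table columns", {
  set.seed(8)
  B <- cbind(rnorm(2000, 6, 3), rnorm(2000, -2, 3))
  ch <- make_toy_chains(B, c("a", "b", "c"), intercept = 100, y_sd = 30)
  row <- summarize_contrast(ch, "method", "a", "b")
  expect_equal(row$relevant_value, 10)  # y_sd / 3
  expect_equal(row$D, mean(contrast_samples(ch, "method", "a", "b")))
  expect_true(row$hpd_low <= row$D && row$D <= row$hpd_high)
  expect_gte(row$pr, 0); expect_lte(row$pr + row$ps, 1)
  expect_true(is.finite(row$mcse_d) && is.finite(row$geweke_z))
  row2 <- summarize_contrast(ch, "method", "a", "b",
                             relevance_config(relevant_value = 5))
  expect_equal(row2$relevant_value, 5)
  expect_gte(row2$pr, row$pr)  # smaller R cannot reduce relevance mass
})
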