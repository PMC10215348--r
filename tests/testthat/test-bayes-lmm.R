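test_that("design dimensions follow the sum-to-zero constraint", {
  # 2 methods, fixed effects only: intercept + exactly 1 method column
  rec <- rbind(make_records(3, method = "A"), make_records(3, method = "B"))
  rec$ejaculate_id <- sprintf("e%d", 1:6)
  d <- build_design(rec, model_spec(fixed_terms = "method",
                                    random_term = NULL))
  expect_equal(ncol(d$X), 2)
  expect_equal(length(d$terms$method$cols), 1)

  # full study design: 1 + (4-1) + (2-1) + (6-1) + 1 = 11 columns
  sim <- generate_dataset(paper_like_config(seed = 3))
  d2 <- build_design(sim$records)
  expect_equal(ncol(d2$X),
               1 + (4 - 1) + (2 - 1) + (6 - 1) + 1)
  expect_equal(length(d2$animal_levels), 10)
  # boar nesting: each animal index maps to exactly one line
  split_lines <- tapply(sim$records$sire_line, sim$records$boar_id,
                        function(x) length(unique(x)))
  expect_true(all(split_lines == 1))
})

test_that("row permutation leaves the design unchanged up to row order", {
  sim <- generate_dataset(paper_like_config(seed = 13))
  d <- build_design(sim$records)
  set.seed(1)
  perm <- sample(nrow(sim$records))
  dp <- build_design(sim$records[perm, ])
  expect_equal(dp$X, d$X[perm, ])
  expect_equal(dp$y, d$y[perm])
  expect_equal(d$animal_levels, dp$animal_levels)
})

test_that("confounded terms are reported as a rank error", {
  rec <- rbind(make_records(4, method = "A"), make_records(4, method = "B"))
  rec$ejaculate_id <- sprintf("e%d", 1:8)
  rec$sire_line <- rep(c("P", "DP"), each = 4)
  rec$month <- rep(c("May", "June"), each = 4)  # aliased with sire_line
  expect_error(build_design(rec, model_spec(
    fixed_terms = c("sire_line", "month"), random_term = NULL)),
    "rank deficient")
})

test_that("missing intervals are mean-imputed at the design stage", {
  rec <- make_records(5)
  rec$interval_days <- c(NA, 6, 7, 8, 9)
  d <- build_design(rec, model_spec(fixed_terms = "interval_days",
                                    random_term = NULL))
  col <- d$X[, "interval_days"]
  expect_equal(col[1], 0)
  expect_equal(col[-1], c(6, 7, 8, 9) - 7.5)
  expect_equal(d$n_interval_imputed, 1L)
})

test_that("known-variance mean model matches the conjugate closed form", {
  set.seed(3)
  n <- 50; sigma <- 2
  rec <- make_records(n, concentration = rnorm(n, 10, sigma))
  spec <- model_spec(fixed_terms = character(0), random_term = NULL,
                     location_mult = 50)
  d <- build_design(rec, spec)
  ch <- gibbs_sample(d, chain_config(4000, 1000, 1, seed = 9),
                     fix_resid_var = sigma^2)
  mu <- ch$samples[, "(Intercept)"]
  ybar <- mean(d$y)
  # posterior is exactly Normal(ybar, sigma^2/n); compare within 3 MCSE
  expect_lt(abs(mean(mu) - ybar), 3 * mcse(mu))
  sd_closed <- sigma / sqrt(n)
  n_draws <- length(mu)
  expect_lt(abs(sd(mu) - sd_closed), 3 * sd_closed / sqrt(2 * n_draws))
  expect_true(all(ch$samples[, "var_resid"] == sigma^2))
})

test_that("zero boar variance is recovered as a near-boundary posterior", {
  sim <- generate_dataset(generator_config(boar_sd = 0,
                                           replicate_count = 1, seed = 11))
  expect_equal(nrow(sim$records), 200)
  ch <- gibbs_sample(build_design(sim$records),
                     chain_config(8000, 2000, 5, seed = 12))
  expect_lt(median(ch$samples[, "var_animal"]),
            median(ch$samples[, "var_resid"]) / 10)
})

test_that("chains are reproducible and respect the variance bounds", {
  sim <- generate_dataset(paper_like_config(seed = 17))
  dat <- aggregate_replicates(sim$records, "mean")
  d <- build_design(dat)
  a <- gibbs_sample(d, chain_config(2000, 500, 5, seed = 77))
  b <- gibbs_sample(d, chain_config(2000, 500, 5, seed = 77))
  expect_identical(a$samples, b$samples)
  for (v in c("var_animal", "var_resid")) {
    expect_true(all(a$samples[, v] >= a$bounds$var_lo))
    expect_true(all(a$samples[, v] <= a$bounds$var_hi))
  }
  expect_false(anyNA(a$samples))
})

test_that("posterior contrasts agree with an independent REML fit", {
  # dual route: Gibbs posterior means vs lme4 generalized least squares
  sim <- generate_dataset(paper_like_config(seed = 19))
  dat <- aggregate_replicates(sim$records, "mean")
  ch <- gibbs_sample(build_design(dat), chain_config(10000, 2000, 10,
                                                     seed = 20))
  dat$method <- factor(dat$method)
  dat$sire_line <- factor(dat$sire_line)
  dat$month <- factor(dat$month)
  dat$interval_c <- ifelse(is.na(dat$interval_days), 0,
                           dat$interval_days -
                             mean(dat$interval_days, na.rm = TRUE))
  contrasts(dat$method) <- contr.sum(nlevels(dat$method))
  contrasts(dat$sire_line) <- contr.sum(2)
  contrasts(dat$month) <- contr.sum(nlevels(dat$month))
  fit <- lme4::lmer(
    concentration ~ method + sire_line + month + interval_c +
      (1 | boar_id), data = dat)
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  C <- contr.sum(4)
  rownames(C) <- levels(dat$method)
  idx <- grep("^method", names(beta))
  for (pair in list(c("Accuread", "ISASv1"), c("iSperm", "OpenCASAv2"))) {
    w <- C[pair[1], ] - C[pair[2], ]
    gls_est <- sum(w * beta[idx])
    gls_se <- sqrt(drop(t(w) %*% V[idx, idx] %*% w))
    s <- contrast_samples(ch, "method", pair[1], pair[2])
    expect_lt(abs(mean(s) - gls_est),
              2 * sqrt(gls_se^2 + var(s)))
  }
})
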