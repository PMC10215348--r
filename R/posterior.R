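#' Relevance configuration for posterior summaries
#'
#' The relevant value R is the smallest difference considered
#' biologically meaningful; the conventional choice is one-third of the
#' trait's raw standard deviation. `relevant_value` may be an explicit
#' number, or `NULL` to use `sd/3` of the analysed response
#' (`y_sd` stored in the chains object).
#'
#' @param hpd_level probability mass of the HPD interval (default 0.95).
#' @param k guarantee probability for the guaranteed value
#'   (default 0.80).
#' @param relevant_value explicit R, or `NULL` for raw trait sd / 3.
#' @return Object of class `relevance_config`.
#' @export
relevance_config <- function(hpd_level = 0.95, k = 0.80,
                             relevant_value = NULL) {
  stopifnot(hpd_level > 0, hpd_level < 1, k > 0, k < 1,
            is.null(relevant_value) || relevant_value > 0)
  structure(list(hpd_level = hpd_level, k = k,
                 relevant_value = relevant_value),
            class = "relevance_config")
}

block_samples <- function(chains, term) {
  stopifnot(inherits(chains, "posterior_chains"))
  info <- chains$terms[[term]]
  if (is.null(info) || info$type != "factor") {
    stop("not a categorical model term: ", term, call. = FALSE)
  }
  info
}

#' Posterior samples of a level effect, level mean, or level contrast
#'
#' Level effects are reconstructed from the sum-to-zero coefficients
#' (`effect(last level) = -sum(others)`); a level mean is intercept +
#' effect; a contrast is `effect(a) - effect(b)` draw by draw.
#'
#' @param chains a [gibbs_sample()] result.
#' @param term categorical model term (e.g. `"method"`).
#' @param level,a,b level labels.
#' @return Numeric vector with one element per retained draw.
#' @export
level_effect_samples <- function(chains, term, level) {
  info <- block_samples(chains, term)
  if (!level %in% info$levels) {
    stop("unknown level '", level, "' for term '", term, "'",
         call. = FALSE)
  }
  drop(chains$samples[, info$cols, drop = FALSE] %*%
         info$contrasts[level, ])
}

#' @rdname level_effect_samples
#' @export
level_mean_samples <- function(chains, term, level) {
  chains$samples[, 1] + level_effect_samples(chains, term, level)
}

#' @rdname level_effect_samples
#' @export
contrast_samples <- function(chains, term, a, b) {
  info <- block_samples(chains, term)
  for (lev in c(a, b)) {
    if (!lev %in% info$levels) {
      stop("unknown level '", lev, "' for term '", term, "'",
           call. = FALSE)
    }
  }
  drop(chains$samples[, info$cols, drop = FALSE] %*%
         (info$contrasts[a, ] - info$contrasts[b, ]))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of sorted samples containing
#' `ceiling(level * n)` draws; ties between equally short windows are
#' broken toward the lowest start.
#'
#' @param samples numeric vector of posterior draws (>= 100 for level
#'   0.95).
#' @param level probability mass (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
hpd <- function(samples, level = 0.95) {
  stopifnot(level > 0, level <= 1)
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 2L) stop("too few samples for an HPD interval", call. = FALSE)
  m <- ceiling(level * n)
  s <- sort(samples)
  if (m >= n) return(c(s[1], s[n]))
  if (n < 100L && level >= 0.9) {
    stop("too few samples (", n, ") for an HPD interval at level ",
         level, call. = FALSE)
  }
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)  # which.min takes the first, i.e. lowest start
  c(s[i], s[i + m - 1L])
}

#' Probability of difference (P0)
#'
#' The posterior probability that a difference is positive when its
#' posterior mean is positive, or negative when the mean is negative;
#' exactly 0.5 when the mean is 0.
#'
#' @param samples posterior draws of the difference.
#' @return Probability in \[0, 1\].
#' @export
p0 <- function(samples) {
  samples <- samples[!is.na(samples)]
  stopifnot(length(samples) > 0)
  m <- mean(samples)
  if (m > 0) mean(samples > 0)
  else if (m < 0) mean(samples < 0)
  else 0.5
}

#' Relevance partition: PR, PS and the opposite tail
#'
#' Splits the posterior of a difference at the relevant value R:
#' `PR` is the mass beyond R on the side of the posterior mean, `PS` the
#' mass with |difference| < R, and `opposite` the mass beyond R on the
#' other side. The three parts sum to 1 exactly (draws exactly at
#' +/- R count toward the adjacent tail).
#'
#' @param samples posterior draws of the difference.
#' @param R relevant value, > 0.
#' @return Named numeric vector `c(PR, PS, opposite)`.
#' @export
relevance_partition <- function(samples, R) {
  stopifnot(R > 0)
  samples <- samples[!is.na(samples)]
  stopifnot(length(samples) > 0)
  n <- length(samples)
  upper <- sum(samples >= R)
  lower <- sum(samples <= -R)
  similar <- n - upper - lower
  if (mean(samples) >= 0) {
    c(PR = upper / n, PS = similar / n, opposite = lower / n)
  } else {
    c(PR = lower / n, PS = similar / n, opposite = upper / n)
  }
}

#' @rdname relevance_partition
#' @export
relevance_prob <- function(samples, R) {
  relevance_partition(samples, R)[["PR"]]
}

#' @rdname relevance_partition
#' @export
similitude_prob <- function(samples, R) {
  relevance_partition(samples, R)[["PS"]]
}

#' Guaranteed value GVk
#'
#' For a positive-mean posterior, the value exceeded with probability
#' `k` (the `1 - k` quantile, so the difference is at least GVk with
#' probability k); for a negative mean, the value undercut with
#' probability `k` (the `k` quantile). At `k = 0.5` this is the median
#' under either convention.
#'
#' @param samples posterior draws.
#' @param k guarantee probability in (0, 1) (default 0.80).
#' @return Numeric scalar.
#' @export
guaranteed_value <- function(samples, k = 0.80) {
  stopifnot(k > 0, k < 1)
  samples <- samples[!is.na(samples)]
  stopifnot(length(samples) > 0)
  if (mean(samples) >= 0) {
    unname(stats::quantile(samples, 1 - k))
  } else {
    unname(stats::quantile(samples, k))
  }
}

# Spectral density of a chain at frequency zero, via an AR fit
# (Yule-Walker, AIC order selection): S(0) = sigma2_pred / (1 - sum phi)^2.
spectrum0 <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  order_max <- max(1L, min(length(x) - 1L, floor(10 * log10(length(x)))))
  fit <- try(stats::ar(x, aic = TRUE, order.max = order_max,
                       method = "yule-walker"), silent = TRUE)
  if (inherits(fit, "try-error")) return(v)
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `frac1` of a chain with the mean of
#' the last `frac2`, standardised by spectral-density-at-zero estimates
#' of each window's variance of the mean:
#' `Z = (mA - mB) / sqrt(S_A(0)/nA + S_B(0)/nB)`.
#' |Z| > 1.96 suggests the chain has not converged.
#'
#' @param x numeric chain (length >= 100).
#' @param frac1 leading fraction (default 0.1).
#' @param frac2 trailing fraction (default 0.5).
#' @return Z score.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100L) stop("chain too short for the Geweke diagnostic",
                     call. = FALSE)
  stopifnot(frac1 > 0, frac2 > 0, frac1 + frac2 <= 1)
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[(n - floor(frac2 * n) + 1L):n]
  va <- spectrum0(a) / length(a)
  vb <- spectrum0(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(0)
    stop("zero spectral variance in a Geweke window", call. = FALSE)
  }
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Monte Carlo standard error by batch means
#'
#' The chain is split into `floor(sqrt(n))` consecutive batches (any
#' remainder is dropped from the end); the MCSE of the chain mean is the
#' standard deviation of the batch means divided by the square root of
#' the number of batches.
#'
#' @param x numeric chain (length >= 100).
#' @return MCSE of the chain mean.
#' @export
mcse <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100L) stop("chain too short for batch-means MCSE", call. = FALSE)
  a <- floor(sqrt(n))
  b <- n %/% a
  bm <- colMeans(matrix(x[seq_len(a * b)], nrow = b, ncol = a))
  stats::sd(bm) / sqrt(a)
}

#' Posterior summary of one factor level
#'
#' Reconstructs the level-mean samples and reports the posterior mean,
#' HPD interval, P0 and guaranteed value, in the layout of the report
#' tables. P0 for a single level is the posterior probability that the
#' level mean exceeds the model's grand mean (the intercept) — an
#' interpretation choice recorded in the output.
#'
#' @param chains a [gibbs_sample()] result.
#' @param term categorical model term.
#' @param level level label.
#' @param config a [relevance_config()].
#' @return One-row data.frame: level, mean, hpd_low, hpd_high, p0, gvk.
#' @export
summarize_level <- function(chains, term, level,
                            config = relevance_config()) {
  s <- level_mean_samples(chains, term, level)
  eff <- level_effect_samples(chains, term, level)
  if (stats::sd(s) == 0) {
    interval <- c(s[1], s[1])
    p0_level <- 0.5
    gv <- s[1]
  } else {
    interval <- hpd(s, config$hpd_level)
    p0_level <- p0(eff)
    gv <- guaranteed_value(s, config$k)
  }
  data.frame(level = level, mean = mean(s),
             hpd_low = interval[1], hpd_high = interval[2],
             p0 = p0_level, gvk = gv,
             stringsAsFactors = FALSE)
}

#' Posterior summary of a pairwise level contrast
#'
#' The report-table row for a difference `a - b`: posterior mean D, HPD
#' interval, P0, probability of relevance PR, probability of similitude
#' PS, guaranteed value GVk, the Monte Carlo standard error of D and
#' the Geweke Z of the contrast chain.
#'
#' @param chains a [gibbs_sample()] result.
#' @param term categorical model term.
#' @param a,b level labels; the contrast is `a - b`.
#' @param config a [relevance_config()]; when its `relevant_value` is
#'   `NULL`, R = (raw response sd)/3 from the analysed dataset.
#' @return One-row data.frame: contrast, D, hpd_low, hpd_high, p0, pr,
#'   ps, gvk, mcse_d, geweke_z, relevant_value.
#' @export
summarize_contrast <- function(chains, term, a, b,
                               config = relevance_config()) {
  s <- contrast_samples(chains, term, a, b)
  R <- config$relevant_value
  if (is.null(R)) R <- chains$y_sd / 3
  interval <- hpd(s, config$hpd_level)
  part <- relevance_partition(s, R)
  data.frame(contrast = paste(a, "-", b), D = mean(s),
             hpd_low = interval[1], hpd_high = interval[2],
             p0 = p0(s), pr = part[["PR"]], ps = part[["PS"]],
             gvk = guaranteed_value(s, config$k),
             mcse_d = mcse(s), geweke_z = geweke_z(s),
             relevant_value = R,
             stringsAsFactors = FALSE)
}
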