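#' Pair two methods' measurements by ejaculate
#'
#' Builds the paired vectors for the agreement statistics: replicates
#' are first collapsed (or kept) via [aggregate_replicates()], then
#' ejaculates measured by both methods are matched.
#'
#' @param records validated measurement records.
#' @param method_a,method_b method labels; `method_a` plays the role of
#'   x (first/reference device) in the agreement functions.
#' @param variable measured variable column (default `"concentration"`).
#' @param policy replicate policy passed to [aggregate_replicates()].
#' @return List of class `paired_measurements` with `x`, `y`,
#'   `ejaculate_id` and the pair labels.
#' @export
pair_methods <- function(records, method_a, method_b,
                         variable = "concentration",
                         policy = c("mean", "keep")) {
  policy <- match.arg(policy)
  records <- aggregate_replicates(records, policy)
  da <- records[records$method == method_a, c("ejaculate_id", "replicate",
                                              variable)]
  db <- records[records$method == method_b, c("ejaculate_id", "replicate",
                                              variable)]
  key_a <- paste(da$ejaculate_id, da$replicate)
  key_b <- paste(db$ejaculate_id, db$replicate)
  common <- intersect(key_a, key_b)
  x <- da[[variable]][match(common, key_a)]
  y <- db[[variable]][match(common, key_b)]
  ok <- !is.na(x) & !is.na(y)
  structure(list(x = x[ok], y = y[ok],
                 ejaculate_id = da$ejaculate_id[match(common, key_a)][ok],
                 method_a = method_a, method_b = method_b,
                 variable = variable),
            class = "paired_measurements")
}

as_pairs <- function(pairs, x = NULL, y = NULL) {
  if (inherits(pairs, "paired_measurements")) return(pairs)
  structure(list(x = pairs, y = y, method_a = "A", method_b = "B",
                 variable = ""), class = "paired_measurements")
}

#' Bland-Altman analysis of two measurement methods
#'
#' Differences are taken as `x - y` ("A - B": first method minus
#' second). The bias is the mean difference, the limits of agreement
#' are `bias +/- multiplier * sd(d)` (sample sd, n - 1), the bias
#' confidence interval is the Student-t interval for the mean
#' difference, and `n_outside` counts points strictly beyond the limits.
#' Zero-variance differences collapse the limits onto the bias; this is
#' flagged, not an error.
#'
#' @param pairs a [pair_methods()] result, or the x vector.
#' @param y y vector when `pairs` is a vector.
#' @param multiplier limits-of-agreement multiplier (default 1.96).
#' @param ci_level bias confidence level (default 0.95).
#' @return Object of class `bland_altman`: bias, loa_low, loa_high,
#'   bias_ci, sd_diff, n, n_outside, loa_collapsed, orientation.
#' @export
bland_altman <- function(pairs, y = NULL, multiplier = 1.96,
                         ci_level = 0.95) {
  pairs <- as_pairs(pairs, y = y)
  d <- pairs$x - pairs$y
  n <- length(d)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  stopifnot(all(is.finite(d)))
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * multiplier * s
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
  ci <- bias + c(-1, 1) * tq * s / sqrt(n)
  structure(list(bias = bias, loa_low = loa[1], loa_high = loa[2],
                 bias_ci = ci, sd_diff = s, n = n,
                 n_outside = sum(d < loa[1] | d > loa[2]),
                 loa_collapsed = s == 0,
                 orientation = paste(pairs$method_a, "-", pairs$method_b)),
            class = "bland_altman")
}

#' Passing-Bablok regression
#'
#' The nonparametric structural regression of the original estimator:
#' all pairwise slopes `(y_j - y_i)/(x_j - x_i)` (pairs with tied x
#' skipped, slopes of exactly -1 excluded), slope = shifted median of
#' the sorted slopes offset by `K`, the number of slopes below -1;
#' intercept = `median(y - slope * x)`. Confidence bounds come from the
#' rank statistic `C = z * sqrt(n (n - 1) (2 n + 5) / 18)`, reading the
#' sorted slopes at ranks `floor((N - C)/2) + K` and
#' `ceiling((N + C)/2) + K + 1`; intercept bounds re-use the slope
#' bounds.
#'
#' @param pairs a [pair_methods()] result, or the x vector.
#' @param y y vector when `pairs` is a vector.
#' @param ci_level confidence level (default 0.95).
#' @return Object of class `passing_bablok`: slope, slope_ci,
#'   intercept, intercept_ci, n, n_slopes_used, n_tied_x_skipped, K.
#' @export
passing_bablok <- function(pairs, y = NULL, ci_level = 0.95) {
  pairs <- as_pairs(pairs, y = y)
  x <- pairs$x
  yv <- pairs$y
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  stopifnot(all(is.finite(x)), all(is.finite(yv)))
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct x values", call. = FALSE)
  }
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- yv[ij[2, ]] - yv[ij[1, ]]
  tied <- dx == 0
  slopes <- dy[!tied] / dx[!tied]
  slopes <- slopes[slopes != -1]
  slopes <- sort(slopes)
  N <- length(slopes)
  if (N < 1L) stop("no usable pairwise slopes", call. = FALSE)
  K <- sum(slopes < -1)

  shifted_median <- function(s, offset) {
    N <- length(s)
    if (N %% 2 == 1) {
      s[(N + 1) / 2 + offset]
    } else {
      (s[N / 2 + offset] + s[N / 2 + 1 + offset]) / 2
    }
  }
  slope <- shifted_median(slopes, K)

  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  lo_idx <- max(1L, floor((N - C) / 2) + K)
  hi_idx <- min(N, ceiling((N + C) / 2) + K + 1)
  slope_ci <- c(slopes[lo_idx], slopes[hi_idx])

  intercept <- stats::median(yv - slope * x)
  intercept_ci <- sort(c(stats::median(yv - slope_ci[2] * x),
                         stats::median(yv - slope_ci[1] * x)))

  structure(list(slope = slope, slope_ci = slope_ci,
                 intercept = intercept, intercept_ci = intercept_ci,
                 n = n, n_slopes_used = N,
                 n_tied_x_skipped = sum(tied), K = K,
                 ci_level = ci_level,
                 orientation = paste(pairs$method_b, "vs",
                                     pairs$method_a)),
            class = "passing_bablok")
}

#' Ordinary least-squares comparison line
#'
#' @param pairs a [pair_methods()] result, or the x vector.
#' @param y y vector when `pairs` is a vector.
#' @return List: slope, intercept, r_squared, n.
#' @export
least_squares_line <- function(pairs, y = NULL) {
  pairs <- as_pairs(pairs, y = y)
  if (length(pairs$x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(pairs$x) == 0) {
    stop("x has zero variance", call. = FALSE)
  }
  fit <- stats::lm(pairs$y ~ pairs$x)
  sst <- sum((pairs$y - mean(pairs$y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = length(pairs$x))
}

#' Paired Student's t-test between two methods
#'
#' Two-sided paired t-test on `x - y`. Differences with zero variance
#' and zero mean return `t = 0, p = 1` by convention (constant nonzero
#' differences return `t = Inf` or `-Inf`, `p = 0`).
#'
#' @param pairs a [pair_methods()] result, or the x vector.
#' @param y y vector when `pairs` is a vector.
#' @return List: t, df, p, mean_diff, n.
#' @export
paired_t <- function(pairs, y = NULL) {
  pairs <- as_pairs(pairs, y = y)
  d <- pairs$x - pairs$y
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    m <- mean(d)
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    return(list(t = t_stat, df = n - 1,
                p = if (m == 0) 1 else 0,
                mean_diff = m, n = n))
  }
  ht <- stats::t.test(pairs$x, pairs$y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate), n = n)
}
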