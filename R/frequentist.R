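#' One-way ANOVA with Fisher's protected LSD post hoc
#'
#' Standard one-way decomposition (via [stats::aov()]) followed by
#' Fisher's least significant difference for every pair of groups:
#' `LSD = t(1 - alpha/2, df_within) * sqrt(MSE * (1/n_i + 1/n_j))`.
#' The LSD is protected: pairs are flagged significant only when the
#' omnibus F test is itself significant at `alpha`.
#'
#' @param values numeric response (e.g. total motility).
#' @param groups grouping labels (e.g. method), same length.
#' @param alpha significance level (default 0.05).
#' @return Object of class `anova_lsd`: `F`, `df_between`, `df_within`,
#'   `p`, `mse`, `group_means` (named), `group_n`, and `lsd_pairs`, a
#'   data.frame with one row per pair (mean difference, LSD threshold,
#'   significance flag).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n_g <- table(groups)
  if (any(n_g < 2L)) {
    stop("every group needs at least 2 observations; too small: ",
         paste(names(n_g)[n_g < 2], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  f_stat <- tab[["F value"]][1]
  p_val <- tab[["Pr(>F)"]][1]
  mse <- tab[["Mean Sq"]][2]
  df_w <- tab[["Df"]][2]
  means <- tapply(values, groups, mean)

  pairs <- utils::combn(levels(groups), 2)
  tq <- stats::qt(1 - alpha / 2, df_w)
  lsd_pairs <- data.frame(
    group_a = pairs[1, ], group_b = pairs[2, ],
    stringsAsFactors = FALSE)
  lsd_pairs$mean_diff <- means[lsd_pairs$group_a] - means[lsd_pairs$group_b]
  lsd_pairs$lsd <- tq * sqrt(mse * (1 / n_g[lsd_pairs$group_a] +
                                      1 / n_g[lsd_pairs$group_b]))
  omnibus_sig <- !is.na(p_val) && p_val < alpha
  lsd_pairs$significant <- omnibus_sig &
    abs(lsd_pairs$mean_diff) > lsd_pairs$lsd
  rownames(lsd_pairs) <- NULL

  structure(list(F = f_stat, df_between = k - 1L, df_within = df_w,
                 p = p_val, mse = mse,
                 group_means = means, group_n = as.vector(n_g),
                 alpha = alpha, lsd_pairs = lsd_pairs),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      format(x$F, digits = 4), ", p = ", format(x$p, digits = 4),
      "\n", sep = "")
  cat("Fisher LSD (protected, alpha = ", x$alpha, "):\n", sep = "")
  print(x$lsd_pairs, digits = 4)
  invisible(x)
}
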