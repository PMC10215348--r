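#' Specification of the Bayesian linear mixed model
#'
#' The concentration model: response = intercept + method + sire line +
#' month + centred inter-collection interval + boar random intercept +
#' residual, with bounded uniform priors on all fixed effects and on
#' both variance components. Categorical blocks use sum-to-zero
#' contrasts, so the intercept is the grand mean and level means are
#' reconstructed as intercept + level effect. The boar enters the model
#' once, as the animal-level random intercept (a fixed boar-within-line
#' block alongside it would be unidentifiable).
#'
#' Default prior bounds are effectively flat but proper: the intercept
#' uniform on mean(y) +/- `location_mult` sd(y), every other fixed
#' effect uniform on 0 +/- `location_mult` sd(y), both variances uniform
#' on (`var_lower`, `var_mult` var(y)).
#'
#' @param response response column name (`"concentration"`,
#'   `"total_motility"` or `"progressive_motility"`).
#' @param fixed_terms fixed-effect terms, a subset of `method`,
#'   `sire_line`, `month` (categorical) and `interval_days` (covariate).
#' @param random_term grouping column for the random intercept, or
#'   `NULL` for a fixed-effects-only model.
#' @param location_mult half-width of location prior bounds, in raw
#'   response standard deviations (default 10).
#' @param var_lower lower bound for both variances (default 1e-6).
#' @param var_mult upper variance bound, in raw response variances
#'   (default 25).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response = "concentration",
                       fixed_terms = c("method", "sire_line", "month",
                                       "interval_days"),
                       random_term = "boar_id",
                       location_mult = 10,
                       var_lower = 1e-6,
                       var_mult = 25) {
  allowed <- c("method", "sire_line", "month", "interval_days")
  bad <- setdiff(fixed_terms, allowed)
  if (length(bad) > 0L) {
    stop("unknown fixed term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(location_mult > 0, var_lower >= 0, var_mult > 0)
  structure(list(response = response, fixed_terms = fixed_terms,
                 random_term = random_term,
                 location_mult = location_mult,
                 var_lower = var_lower, var_mult = var_mult),
            class = "model_spec")
}

#' Build design matrices for the mixed model
#'
#' Encodes categorical fixed terms with sum-to-zero contrasts (levels in
#' alphabetical order; the last level's effect is minus the sum of the
#' others), centres the interval covariate at its observed mean and
#' gives rows with a missing interval the centred value 0 (mean
#' imputation at the design stage), and indexes the random grouping so
#' that boars are nested within line by construction (each boar id
#' belongs to one line).
#'
#' @param records validated measurement records.
#' @param spec a [model_spec()].
#' @return Object of class `semen_design`: the fixed-effect matrix `X`,
#'   response `y`, 1-based `animal` index with `animal_levels`, a
#'   `terms` map for level reconstruction, and the raw response mean/sd
#'   used for default prior bounds and relevant values.
#' @export
build_design <- function(records, spec = model_spec()) {
  records <- validate_records(records)
  y_all <- records[[spec$response]]
  if (is.null(y_all)) {
    stop("response column not present: ", spec$response, call. = FALSE)
  }
  keep <- !is.na(y_all)
  if (!any(keep)) stop("no non-missing response values", call. = FALSE)
  records <- records[keep, , drop = FALSE]
  y <- y_all[keep]
  n <- length(y)

  X <- matrix(1, n, 1)
  colnames(X) <- "(Intercept)"
  terms <- list()
  n_imputed <- 0L
  for (term in spec$fixed_terms) {
    if (term == "interval_days") {
      v <- records$interval_days
      centre <- mean(v, na.rm = TRUE)
      n_imputed <- sum(is.na(v))
      v <- ifelse(is.na(v), 0, v - centre)
      X <- cbind(X, interval_days = v)
      terms[[term]] <- list(type = "covariate", centre = centre,
                            cols = ncol(X))
    } else {
      f <- factor(records[[term]])
      L <- nlevels(f)
      if (L < 2L) {
        stop("categorical term has a single level: ", term, call. = FALSE)
      }
      C <- stats::contr.sum(L)
      rownames(C) <- levels(f)
      M <- C[as.integer(f), , drop = FALSE]
      colnames(M) <- paste0(term, ".", levels(f)[-L])
      cols <- ncol(X) + seq_len(L - 1L)
      X <- cbind(X, M)
      terms[[term]] <- list(type = "factor", levels = levels(f),
                            contrasts = C, cols = cols)
    }
  }
  rownames(X) <- NULL

  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design is rank deficient after the sum-to-zero constraint; ",
         "confounded column(s): ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }

  animal <- NULL
  animal_levels <- character()
  if (!is.null(spec$random_term)) {
    g <- factor(records[[spec$random_term]])
    if (nlevels(g) < 3L) {
      stop("random term needs at least 3 groups for a proper variance ",
           "conditional; got ", nlevels(g), call. = FALSE)
    }
    animal <- as.integer(g)
    animal_levels <- levels(g)
  }

  structure(list(X = X, y = y, animal = animal,
                 animal_levels = animal_levels,
                 terms = terms, spec = spec,
                 n_interval_imputed = n_imputed,
                 y_mean = mean(y), y_sd = stats::sd(y),
                 row_index = which(keep)),
            class = "semen_design")
}

#' Gibbs chain configuration
#'
#' @param n_iter total iterations (default 50000).
#' @param burn_in discarded initial iterations (default 10000).
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param seed integer RNG seed.
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(n_iter = 50000, burn_in = 10000, thin = 10,
                         seed = 1L) {
  stopifnot(burn_in >= 0, burn_in < n_iter, thin >= 1,
            (n_iter - burn_in) >= thin)
  structure(list(n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_config")
}

#' Draw from the posterior of the mixed model by Gibbs sampling
#'
#' Systematic-scan Gibbs sampler: each fixed effect is drawn from its
#' normal full conditional truncated to its uniform prior bounds
#' (inverse-CDF sampling, so nothing is rejected); animal intercepts
#' from their normal full conditionals; both variances from
#' inverse-gamma full conditionals truncated to their bounds. Retained
#' samples are post-burn-in and thinned. Chains are bit-reproducible
#' given `chain$seed`.
#'
#' A warning is raised when the least-squares solution falls outside the
#' location prior bounds (the truncation would then bite).
#'
#' @param design a [build_design()] result.
#' @param chain a [chain_config()].
#' @param fix_resid_var optional positive value at which the residual
#'   variance is held fixed (for validation against conjugate
#'   closed-form posteriors); `NULL` to sample it.
#' @return Object of class `posterior_chains`: `samples` (matrix, one
#'   column per parameter: fixed effects, animal effects `u.*`,
#'   `var_animal`, `var_resid`), the `terms` map, prior `bounds`, the
#'   chain configuration and raw response scale.
#' @export
gibbs_sample <- function(design, chain = chain_config(),
                         fix_resid_var = NULL) {
  stopifnot(inherits(design, "semen_design"),
            inherits(chain, "chain_config"))
  spec <- design$spec
  X <- design$X
  p <- ncol(X)
  half <- spec$location_mult * design$y_sd
  beta_lo <- rep(-half, p)
  beta_hi <- rep(half, p)
  beta_lo[1] <- design$y_mean - half
  beta_hi[1] <- design$y_mean + half
  var_lo <- spec$var_lower
  var_hi <- spec$var_mult * stats::var(design$y)

  ols <- stats::lm.fit(X, design$y)$coefficients
  if (any(ols < beta_lo | ols > beta_hi)) {
    warning("least-squares solution outside the location prior bounds; ",
            "consider a larger location_mult", call. = FALSE)
  }

  include_animal <- !is.null(design$animal)
  n <- length(design$y)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)

  beta_init <- pmin(pmax(ols, beta_lo), beta_hi)
  var_init <- min(max(stats::var(design$y) / 2, var_lo * 2), var_hi / 2)

  set.seed(chain$seed)
  samples <- gibbs_lmm_cpp(
    X, if (include_animal) design$animal - 1L else integer(n),
    length(design$animal_levels), design$y,
    beta_lo, beta_hi, beta_init,
    var_lo, var_hi, var_lo, var_hi,
    var_init, var_init,
    chain$n_iter, chain$burn_in, chain$thin,
    if (is.null(fix_resid_var)) -1 else fix_resid_var,
    include_animal)

  cn <- colnames(X)
  if (include_animal) {
    cn <- c(cn, paste0("u.", design$animal_levels), "var_animal")
  }
  cn <- c(cn, "var_resid")
  colnames(samples) <- cn

  structure(list(samples = samples, terms = design$terms,
                 bounds = list(beta_lo = beta_lo, beta_hi = beta_hi,
                               var_lo = var_lo, var_hi = var_hi),
                 chain = chain, response = spec$response,
                 y_mean = design$y_mean, y_sd = design$y_sd,
                 n_obs = n, fix_resid_var = fix_resid_var),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat("Posterior chains for response '", x$response, "': ",
      nrow(x$samples), " retained draws x ", ncol(x$samples),
      " parameters\n", sep = "")
  cat("  chain: ", x$chain$n_iter, " iterations, burn-in ",
      x$chain$burn_in, ", thinning ", x$chain$thin,
      ", seed ", x$chain$seed, "\n", sep = "")
  invisible(x)
}
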