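# Fixture builders shared across test files.

# Minimal well-formed measurement records.
make_records <- function(n = 3, method = "ISASv1", concentration = 100 + seq_len(n),
                         total = 60, progressive = 40) {
  data.frame(
    ejaculate_id = sprintf("e%03d", seq_len(n)),
    boar_id = "b1",
    sire_line = "Pietrain",
    month = "May",
    interval_days = 7,
    method = method,
    replicate = 1L,
    concentration = concentration,
    total_motility = total,
    progressive_motility = progressive,
    stringsAsFactors = FALSE)
}

# A hand-constructable posterior_chains object: one categorical term with
# sum-to-zero coding, plus an intercept column. `B` is the retained-draw
# matrix of the term's coefficients (draws x (L-1)).
make_toy_chains <- function(B, levels, intercept = 0, y_sd = 1) {
  B <- as.matrix(B)
  L <- length(levels)
  stopifnot(ncol(B) == L - 1)
  C <- stats::contr.sum(L)
  rownames(C) <- levels
  samples <- cbind(rep(intercept, nrow(B)), B)
  colnames(samples) <- c("(Intercept)",
                         paste0("method.", levels[-L]))
  structure(list(
    samples = samples,
    terms = list(method = list(type = "factor", levels = levels,
                               contrasts = C, cols = 1 + seq_len(L - 1))),
    y_mean = intercept, y_sd = y_sd,
    response = "toy"),
    class = "posterior_chains")
}

# Deterministic Gaussian sample (quantile grid) for near-exact checks of
# sample-based summaries against closed-form normal quantities.
gaussian_grid <- function(n, mean = 0, sd = 1) {
  stats::qnorm(stats::ppoints(n), mean, sd)
}

# O(n^2)-style brute-force shortest-window HPD used as the independent
# oracle for hpd().
brute_hpd <- function(x, level) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(level * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    lo <- s[i]
    hi <- s[i + m - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# Independent Passing-Bablok slope oracle: exhaustive slope enumeration
# and direct shifted-median selection.
brute_pb_slope <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] != x[j]) {
        s <- (y[j] - y[i]) / (x[j] - x[i])
        if (s != -1) slopes <- c(slopes, s)
      }
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  if (N %% 2 == 1) slopes[(N + 1) / 2 + K]
  else mean(slopes[c(N / 2 + K, N / 2 + 1 + K)])
}

default_methods <- c("Accuread", "ISASv1", "iSperm", "OpenCASAv2")
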