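# Independent oracles used to cross-check the implementation.

# Brute-force grid search for the burst model: profile (A, C) linearly at
# every node of a (k_chem, k_cat) grid, keep the least-squares winner, and
# zoom in around it for `rounds` refinement passes. Entirely independent of
# the package's optimizer path.
grid_burst_oracle <- function(t, y, direction,
                              k_range = c(0.4, 10) / stats::median(t),
                              n_k = 80, kcat_range = NULL, n_kcat = 41,
                              rounds = 3) {
  if (is.null(kcat_range)) {
    span <- abs(diff(range(y))) / max(t)
    kcat_range <- c(-2 * span, 2 * span)
  }
  scan <- function(ks, bs, best) {
    for (k in ks) {
      ex <- exp(-k * t)
      for (b in bs) {
        yy <- y - b * t
        fit <- .lm.fit(cbind(1, ex), yy)
        rss <- sum(fit$residuals^2)
        if (rss < best$rss)
          best <- list(rss = rss, k_chem = k, b = b,
                       C = fit$coefficients[1], A = fit$coefficients[2])
      }
    }
    best
  }
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_k))
  bs <- seq(kcat_range[1], kcat_range[2], length.out = n_kcat)
  log_k_step <- diff(log(ks[1:2]))
  coarse_log_k_step <- log_k_step
  b_step <- diff(bs[1:2])
  best <- scan(ks, bs, list(rss = Inf))
  for (r in seq_len(rounds)) {
    ks <- exp(seq(log(best$k_chem) - 1.5 * log_k_step,
                  log(best$k_chem) + 1.5 * log_k_step, length.out = 15))
    bs <- seq(best$b - 1.5 * b_step, best$b + 1.5 * b_step, length.out = 15)
    log_k_step <- diff(log(ks[1:2]))
    b_step <- diff(bs[1:2])
    best <- scan(ks, bs, best)
  }
  best$k_cat <- if (direction == "decay") -best$b else best$b
  best$log_k_step <- coarse_log_k_step
  best
}

# Closed-form contrasts for a saturated 2x2 design under wt01 coding:
# cell means and their differences. OLS with interaction must agree.
contrast_oracle <- function(d) {
  cm <- function(h, k) mean(d$y_obs[d$hvgh_wt == h & d$kmsks_wt == k])
  y00 <- cm(0, 0); y10 <- cm(1, 0); y01 <- cm(0, 1); y11 <- cm(1, 1)
  c(beta0 = y00, beta_H = y10 - y00, beta_K = y01 - y00,
    beta_HK = y11 - y10 - y01 + y00)
}

# Hand least-squares formulas for simple regression.
simple_regression_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Hand Pearson correlation.
pearson_oracle <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Construct a burst_fit object directly (for estimator-level tests that do
# not need an optimizer run).
fake_burst_fit <- function(A, C, species = "ATP", k_chem = 0.02,
                           k_cat = 1e-4, variant_id = "V", replicate = 1L) {
  structure(
    list(variant_id = variant_id, replicate = as.integer(replicate),
         species = species,
         direction = if (species == "ATP") "decay" else "rise",
         A = A, k_chem = k_chem, k_cat = k_cat, C = C,
         standard_errors = c(A = NA_real_, k_chem = NA_real_,
                             k_cat = NA_real_, C = NA_real_),
         r_squared = 1, residuals = numeric(0), converged = TRUE),
    class = "burst_fit")
}

# Four-corner table (one or more replicates per corner) from corner means.
corners_to_dataset <- function(y00, y10, y01, y11, coding = "wt01") {
  factorial_dataset(tibble::tibble(
    hvgh_wt = c(0, 1, 0, 1), kmsks_wt = c(0, 0, 1, 1),
    y_obs = c(y00, y10, y01, y11)), coding = coding)
}
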