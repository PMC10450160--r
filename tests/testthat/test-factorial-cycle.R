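test_that("a constant response yields intercept only and flagged R2", {
  d <- factorial_dataset(tibble::tibble(
    hvgh_wt = rep(c(0, 1, 0, 1), 2), kmsks_wt = rep(c(0, 0, 1, 1), 2),
    y_obs = 2.5))
  fit <- fit_cycle(d)
  expect_equal(unname(coef(fit)), c(2.5, 0, 0, 0), tolerance = 1e-12)
  expect_true(is.na(fit$r_squared))
})

test_that("corners built from the signature coefficients are refit exactly", {
  # wt01, intercept 0: double mutant 0, AMSAS 0.45, AVGA -0.32,
  # WT 0 + 0.45 - 0.32 + 0.36
  d <- corners_to_dataset(0, 0.45, -0.32, 0.45 - 0.32 + 0.36)
  fit <- fit_cycle(d)
  expect_equal(unname(coef(fit)),
               c(0, 0.45, -0.32, 0.36), tolerance = 1e-12)
  # the regression interaction is the double-mutant arithmetic
  expect_equal(cycle_view(fit)$coupling, 0.36, tolerance = 1e-12)
})

test_that("saturated OLS equals closed-form contrasts (property)", {
  set.seed(17)
  for (i in 1:30) {
    reps <- sample(1:3, 1)
    d <- factorial_dataset(tibble::tibble(
      hvgh_wt = rep(c(0, 1, 0, 1), each = reps),
      kmsks_wt = rep(c(0, 0, 1, 1), each = reps),
      y_obs = rnorm(4 * reps, sd = 2)))
    expect_equal(coef(fit_cycle(d)), contrast_oracle(d), tolerance = 1e-10)
  }
})

test_that("double-mutant coupling implements the corner arithmetic", {
  corners <- c(WT = 0.49, AVGA = -0.32, AMSAS = 0.45, AVGA_AMSAS = 0)
  expect_equal(double_mutant_coupling(corners), 0.36, tolerance = 1e-12)
  # additive corners: no coupling
  add <- c(WT = 0.45 + (-0.32) - 0, AVGA = -0.32, AMSAS = 0.45,
           AVGA_AMSAS = 0)
  expect_equal(double_mutant_coupling(add), 0, tolerance = 1e-12)
  expect_error(double_mutant_coupling(c(WT = 1, AVGA = 2)), "AMSAS")
})

test_that("coupling equals the wt01 interaction coefficient on any data", {
  set.seed(23)
  for (i in 1:10) {
    d <- factorial_dataset(tibble::tibble(
      hvgh_wt = rep(c(0, 1, 0, 1), each = 3),
      kmsks_wt = rep(c(0, 0, 1, 1), each = 3),
      y_obs = rnorm(12, mean = 3)))
    fit <- fit_cycle(d)
    expect_equal(double_mutant_coupling(cycle_corners(fit)),
                 coef(fit)[["beta_HK"]], tolerance = 1e-12)
  }
})

test_that("recoding is an exact reparameterization", {
  d <- corners_to_dataset(0.1, 0.8, -0.4, 1.1)
  fit <- fit_cycle(d)
  # effect coding scales the interaction by 1/4
  eff <- recode(fit, "effect_pm1")
  expect_equal(coef(eff)[["beta_HK"]], coef(fit)[["beta_HK"]] / 4,
               tolerance = 1e-12)
  # corner predictions are invariant under every coding
  for (cd in c("mut01", "effect_pm1")) {
    expect_equal(cycle_corners(recode(fit, cd)), cycle_corners(fit),
                 tolerance = 1e-12)
  }
  # involution: recoding back restores the coefficients
  back <- recode(recode(fit, "mut01"), "wt01")
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_equal(back$vcov, fit$vcov, tolerance = 1e-10)
  # coupling magnitude is coding-invariant after the documented scale change
  expect_equal(4 * coef(eff)[["beta_HK"]],
               double_mutant_coupling(cycle_corners(eff)), tolerance = 1e-12)
  expect_error(recode(fit, "banana"))
})

test_that("recoded fits keep valid standard errors", {
  set.seed(31)
  d <- simulate_factorial_rates(
    factorial_truth(beta0 = 3, beta_H = 0.5, beta_HK = -1, noise_sd = 0.1,
                    n_replicates = 3), seed = 31)
  fit <- fit_cycle(d)
  # refitting under the target coding is the reference for the vcov map
  refit <- fit_cycle(recode(d, "effect_pm1"))
  mapped <- recode(fit, "effect_pm1")
  expect_equal(coef(mapped), coef(refit), tolerance = 1e-10)
  expect_equal(mapped$coefficients$se, refit$coefficients$se,
               tolerance = 1e-10)
  expect_equal(mapped$coefficients$p, refit$coefficients$p,
               tolerance = 1e-8)
})

test_that("cycle edges telescope to zero and corners match cell means", {
  set.seed(5)
  d <- simulate_factorial_rates(
    factorial_truth(beta0 = 2, beta_H = 0.4, beta_K = -0.3, beta_HK = 0.2,
                    noise_sd = 0.2, n_replicates = 3), seed = 5)
  fit <- fit_cycle(d)
  v <- cycle_view(fit)
  expect_equal(sum(v$edges), 0, tolerance = 1e-12)
  cell_mean <- function(h, k) mean(d$y_obs[d$hvgh_wt == h & d$kmsks_wt == k])
  expect_equal(unname(v$corners["WT"]), cell_mean(1, 1), tolerance = 1e-10)
  expect_equal(unname(v$corners["AVGA_AMSAS"]), cell_mean(0, 0),
               tolerance = 1e-10)
})

test_that("a missing corner is a hard error naming the combination", {
  d <- tibble::tibble(hvgh_wt = c(0, 1, 0), kmsks_wt = c(0, 0, 1),
                      y_obs = 1:3)
  expect_error(factorial_dataset(d), "1 1")
  expect_error(factorial_dataset(
    tibble::tibble(hvgh_wt = 1, kmsks_wt = 1, y_obs = Inf)), "finite")
})

test_that("studentized residuals screen stays within (-4, 4) when the model holds", {
  set.seed(41)
  n_out <- 0; n_tot <- 0
  for (i in 1:150) {
    d <- simulate_factorial_rates(
      factorial_truth(beta0 = 3, beta_H = 0.45, beta_K = -0.32,
                      beta_HK = 0.36, noise_sd = 0.1, n_replicates = 3))
    st <- fit_cycle(d)$studentized_residuals
    n_out <- n_out + sum(abs(st) >= 4)
    n_tot <- n_tot + length(st)
  }
  expect_gte(1 - n_out / n_tot, 0.99)
})

test_that("the 2^3 factorial fitter recovers declared effects", {
  g <- expand.grid(hvgh_wt = 0:1, kmsks_wt = 0:1, full_length = 0:1)
  # wt01 truth: intercept 1, main effects 0.5/-0.3/2, one 2-way interaction
  g$y_obs <- 1 + 0.5 * g$hvgh_wt - 0.3 * g$kmsks_wt + 2 * g$full_length +
    0.36 * g$hvgh_wt * g$kmsks_wt
  fit <- fit_factorial(g, c("hvgh_wt", "kmsks_wt", "full_length"))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["intercept"]], 1, tolerance = 1e-10)
  expect_equal(est[["full_length"]], 2, tolerance = 1e-10)
  expect_equal(est[["hvgh_wt:kmsks_wt"]], 0.36, tolerance = 1e-10)
  expect_equal(est[["hvgh_wt:kmsks_wt:full_length"]], 0, tolerance = 1e-10)

  # two-factor case agrees with fit_cycle
  d <- simulate_factorial_rates(
    factorial_truth(beta0 = 2, beta_H = 0.4, beta_HK = -0.7, noise_sd = 0.1,
                    n_replicates = 3), seed = 13)
  f2 <- fit_factorial(d, c("hvgh_wt", "kmsks_wt"))
  est2 <- setNames(f2$coefficients$estimate, f2$coefficients$term)
  expect_equal(unname(est2), unname(coef(fit_cycle(d))), tolerance = 1e-10)

  expect_error(fit_factorial(g[g$full_length == 1, ],
                             c("hvgh_wt", "kmsks_wt", "full_length")),
               "combinations")
})
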