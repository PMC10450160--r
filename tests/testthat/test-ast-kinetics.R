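test_that("noiseless burst parameters are recovered to 1e-6 relative error", {
  cases <- list(
    list(sp = "ATP", n = 0.5, k = 0.01, kc = 1e-4),
    list(sp = "ATP", n = 0.66, k = 0.05, kc = 5e-4),
    list(sp = "ADP", n = 0.50, k = 0.02, kc = 1e-4),
    list(sp = "AMP", n = 0.16, k = 0.005, kc = 2e-5))
  for (cs in cases) {
    tk <- true_kinetics("V", cs$sp, cs$n, cs$k, cs$kc)
    fit <- fit_burst(simulate_timecourse(tk, noise_sd = 0))
    expect_true(fit$converged)
    expect_equal(fit$k_chem, cs$k, tolerance = 1e-6)
    expect_equal(fit$k_cat, cs$kc, tolerance = 1e-6)
    if (cs$sp == "ATP") {
      expect_equal(fit$A, cs$n, tolerance = 1e-6)
      expect_equal(fit$C, 1 - cs$n, tolerance = 1e-6)
    } else {
      # rise curves share the decay parameterization with A = -n, C = n
      expect_equal(fit$A, -cs$n, tolerance = 1e-6)
      expect_equal(fit$C, cs$n, tolerance = 1e-6)
    }
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_length(fit$residuals, 16)
  }
})

test_that("zero-noise round trips hold across random parameter draws", {
  set.seed(42)
  for (i in 1:8) {
    n <- runif(1, 0.1, 0.9)
    k <- 10^runif(1, -2.5, -1)
    kc <- 10^runif(1, -5, -3.5)
    sp <- sample(c("ATP", "ADP"), 1)
    tk <- true_kinetics("V", sp, n, k, kc)
    fit <- fit_burst(simulate_timecourse(tk, noise_sd = 0))
    expect_equal(fit$k_chem, k, tolerance = 1e-6)
    expect_equal(abs(fit$A), n, tolerance = 1e-5)
  }
})

test_that("optimizer matches the grid-search oracle on noisy data", {
  set.seed(99)
  for (i in 1:3) {
    tk <- true_kinetics("V", "ATP", runif(1, 0.3, 0.7),
                        10^runif(1, -2, -1.3), 1e-4)
    tc <- simulate_timecourse(tk, noise_sd = 0.01)
    fit <- fit_burst(tc)
    oracle <- grid_burst_oracle(tc$seconds, tc$fraction, "decay")
    expect_lt(abs(log(fit$k_chem) - log(oracle$k_chem)), oracle$log_k_step)
    expect_lte(sum(fit$residuals^2), oracle$rss + 1e-10)
  }
})

test_that("degenerate inputs raise errors; optimizer failure is a state", {
  cond <- assay_conditions()
  flat <- timecourse("V", 1, "ATP", 1:6, rep(0.5, 6), cond)
  expect_error(fit_burst(flat), "all-constant")
  expect_error(timecourse("V", 1, "ATP", 1:4, rep(0.5, 4), cond),
               "at least 5")
  bad <- fake_burst_fit(0.4, 0.6)
  bad$converged <- FALSE
  expect_error(n_values(bad), "converged")
})

test_that("n-value estimators implement the titration arithmetic", {
  cond <- assay_conditions(atp_total = 5, enzyme_total = 3)
  # decay: n = A [ATP]/[E] and n = (1 - C) [ATP]/[E]
  nv <- n_values(fake_burst_fit(A = 0.40, C = 0.60, species = "ATP"), cond)
  expect_equal(unname(nv["n_from_A"]), 0.40 * 5 / 3, tolerance = 1e-12)
  expect_equal(unname(nv["n_from_C"]), (1 - 0.60) * 5 / 3, tolerance = 1e-12)
  expect_equal(nv[["n_from_A"]], nv[["n_from_C"]])

  # rise: C carries the burst; |A| is the default amplitude companion
  nvr <- n_values(fake_burst_fit(A = -0.16, C = 0.16, species = "AMP"), cond)
  expect_equal(unname(nvr["n_from_C"]), 0.16 * 5 / 3, tolerance = 1e-12)
  expect_equal(unname(nvr["n_from_A"]), 0.16 * 5 / 3, tolerance = 1e-12)

  # the alternative printed convention for the rise amplitude is explicit
  nvr2 <- n_values(fake_burst_fit(A = -0.16, C = 0.16, species = "AMP"),
                   cond, rise_a_convention = "one_minus")
  expect_equal(unname(nvr2["n_from_A"]), (1 - (-0.16)) * 5 / 3,
               tolerance = 1e-12)
})

test_that("estimator agreement is exact on model-exact data", {
  tk <- true_kinetics("V", "ATP", 0.4, 0.02, 1e-4)
  fit <- fit_burst(simulate_timecourse(tk, noise_sd = 0))
  nv <- n_values(fit)
  expect_equal(nv[["n_from_A"]], nv[["n_from_C"]], tolerance = 1e-6)
})

test_that("aggregation pools replicates and estimators per species", {
  cond <- assay_conditions(5, 3)
  # one fit whose two estimators are 0.64 and 0.69
  f <- fake_burst_fit(A = 0.64 * 3 / 5, C = 1 - 0.69 * 3 / 5, species = "ATP")
  fr <- fake_burst_fit(A = -0.3, C = 0.3, species = "ADP")
  fm <- fake_burst_fit(A = -0.2, C = 0.2, species = "AMP")
  agg <- aggregate_n(list(f, fr, fm), cond)
  expect_equal(agg$n_T, mean(c(0.64, 0.69)), tolerance = 1e-12)
  atp_row <- agg$species[agg$species$species == "ATP", ]
  expect_equal(atp_row$n_sd, sd(c(0.64, 0.69)), tolerance = 1e-12)
  expect_equal(round(atp_row$n_sd, 4), 0.0354)
  expect_equal(agg$n_D, 0.3 * 5 / 3, tolerance = 1e-12)

  # non-converged fits are skipped and counted
  dead <- fake_burst_fit(0.4, 0.6, species = "ATP", replicate = 2L)
  dead$converged <- FALSE
  agg2 <- aggregate_n(list(f, dead, fr, fm), cond)
  expect_equal(agg2$species$n_skipped[agg2$species$species == "ATP"], 1L)
  expect_equal(agg2$n_T, agg$n_T)

  # a species with no converged fit is a hard error
  only_dead <- fake_burst_fit(-0.3, 0.3, species = "ADP")
  only_dead$converged <- FALSE
  expect_error(aggregate_n(list(f, only_dead), cond), "no converged fits")
})

test_that("fitted n-values respect conservation end to end", {
  vt <- variant_truth("WT", n_D = 0.50 * 3 / 5, n_M = 0.16 * 3 / 5,
                      k_chem = 0.02, k_cat = 1e-4)
  tcs <- simulate_variant_set(vt, noise_sd = 0.01, n_replicates = 3,
                              seed = 5)
  agg <- aggregate_n(lapply(tcs, fit_burst))
  expect_lt(abs(agg$n_T - (agg$n_D + agg$n_M)) / agg$n_T, 0.02)
  expect_equal(agg$n_T, 0.66, tolerance = 0.05)
})
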