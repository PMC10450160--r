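#' Ground-truth kinetic parameters for one species of one variant
#'
#' Describes the generating model behind a single-turnover time course: a
#' first-order burst of amplitude `n_frac` (fraction of total ATP) with rate
#' `k_chem`, followed by linear steady-state turnover at rate `k_cat`. ATP
#' curves decay from 1; product curves (ADP, AMP, acyl-tRNA) rise from 0.
#'
#' @param variant_id Variant label.
#' @param species One of "ATP", "ADP", "AMP", "AA_TRNA".
#' @param n_frac Burst fraction of total ATP, in [0, 1].
#' @param k_chem First-order burst rate constant, per second; > 0.
#' @param k_cat Steady-state rate, fraction per second; >= 0.
#' @param direction "decay" or "rise"; inferred from `species` by default.
#' @return An object of class `true_kinetics`.
#' @export
true_kinetics <- function(variant_id, species, n_frac, k_chem, k_cat = 0,
                          direction = NULL) {
  species <- match.arg(species, VALID_SPECIES)
  if (!is.numeric(n_frac) || n_frac < 0 || n_frac > 1)
    stop("`n_frac` must lie in [0, 1]")
  if (!is.numeric(k_chem) || k_chem <= 0)
    stop("`k_chem` must be positive (s^-1)")
  if (!is.numeric(k_cat) || k_cat < 0)
    stop("`k_cat` must be non-negative (fraction s^-1)")
  if (is.null(direction)) direction <- species_direction(species)
  direction <- match.arg(direction, c("decay", "rise"))
  structure(
    list(variant_id = as.character(variant_id), species = species,
         n_frac = n_frac, k_chem = k_chem, k_cat = k_cat,
         direction = direction),
    class = "true_kinetics"
  )
}

# Noiseless burst model. Decay: starts at 1, loses n_frac exponentially,
# then declines linearly. Rise: starts at 0, gains n_frac, then climbs.
burst_model <- function(truth, t) {
  burst <- truth$n_frac * (1 - exp(-truth$k_chem * t))
  if (truth$direction == "decay") 1 - burst - truth$k_cat * t
  else burst + truth$k_cat * t
}

#' Default sampling grid for a burst time course
#'
#' 16 points: 12 near-geometric times covering 0.1/k_chem to 5/k_chem (the
#' burst phase) plus a 4-point linear tail out to 12/k_chem (the steady
#' state), so both the exponential and the linear regime are resolved.
#'
#' @param k_chem Burst rate constant, s^-1.
#' @param n_points Total number of points (>= 8). Default 16.
#' @return Strictly increasing numeric vector of times, seconds.
#' @export
default_time_grid <- function(k_chem, n_points = 16) {
  if (k_chem <= 0) stop("`k_chem` must be positive")
  if (n_points < 8) stop("need at least 8 points")
  n_geo <- n_points - 4
  geo <- exp(seq(log(0.1 / k_chem), log(5 / k_chem), length.out = n_geo))
  tail <- seq(6.5 / k_chem, 12 / k_chem, length.out = 4)
  c(geo, tail)
}

#' Simulate a single-turnover time course
#'
#' Evaluates the exponential-burst + linear model at the requested times and
#' adds homoscedastic Gaussian noise on the fraction scale. Values are not
#' clipped to [0, 1]: the generator preserves the model's linearity so that
#' fits to noisy data remain unbiased.
#'
#' @param truth A [true_kinetics()] object.
#' @param times Strictly increasing times, seconds; at least 5 points
#'   spanning at least 3/k_chem. Default [default_time_grid()].
#' @param noise_sd Gaussian noise standard deviation (fraction scale); >= 0.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param replicate Replicate index stored on the result.
#' @param conditions [assay_conditions()] stored on the result.
#' @return A [timecourse()] object.
#' @examples
#' tk <- true_kinetics("WT", "ATP", n_frac = 0.66, k_chem = 0.02, k_cat = 1e-4)
#' tc <- simulate_timecourse(tk, noise_sd = 0.01, seed = 1)
#' @export
simulate_timecourse <- function(truth, times = default_time_grid(truth$k_chem),
                                noise_sd = 0, seed = NULL, replicate = 1L,
                                conditions = assay_conditions()) {
  if (!inherits(truth, "true_kinetics"))
    stop("`truth` must be created by true_kinetics()")
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (length(times) < 5) stop("need at least 5 time points")
  if (max(times) * truth$k_chem < 3)
    stop("`times` must span at least 3/k_chem to resolve the burst")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  y <- burst_model(truth, times)
  if (noise_sd > 0) y <- y + stats::rnorm(length(times), 0, noise_sd)
  timecourse(truth$variant_id, replicate, truth$species, times, y, conditions)
}

#' Build nucleotide-conserving ground truth for one variant
#'
#' Convenience constructor for the three-species truth of one variant: the
#' ATP burst fraction is n_D + n_M by construction, all species share one
#' k_chem, and the steady-state rate is partitioned between ADP and AMP in
#' proportion to their burst fractions so that mass balance holds at every
#' time point, not just in the burst.
#'
#' @param variant_id Variant label.
#' @param n_D,n_M Burst fractions appearing as ADP and AMP.
#' @param k_chem Shared first-order rate, s^-1.
#' @param k_cat Total steady-state ATP consumption rate, fraction s^-1.
#' @return List of three [true_kinetics()] (ATP, ADP, AMP).
#' @export
variant_truth <- function(variant_id, n_D, n_M, k_chem, k_cat = 0) {
  n_T <- n_D + n_M
  if (n_T > 1) stop("n_D + n_M must not exceed 1")
  if (n_T <= 0) stop("n_D + n_M must be positive")
  list(
    ATP = true_kinetics(variant_id, "ATP", n_T, k_chem, k_cat),
    ADP = true_kinetics(variant_id, "ADP", n_D, k_chem, k_cat * n_D / n_T),
    AMP = true_kinetics(variant_id, "AMP", n_M, k_chem, k_cat * n_M / n_T)
  )
}

#' Simulate replicated three-species time courses for one variant
#'
#' Generates ATP, ADP and AMP curves for one variant. The truths must
#' conserve nucleotides (n_ATP = n_ADP + n_AMP, shared k_chem, partitioned
#' k_cat) so that, noiselessly, ATP loss equals ADP gain plus AMP gain at
#' every time point.
#'
#' @param truths Named list with elements ATP, ADP, AMP, each a
#'   [true_kinetics()]; see [variant_truth()].
#' @param conditions [assay_conditions()] shared by all curves.
#' @param noise_sd Gaussian noise sd (fraction scale).
#' @param n_replicates Number of replicates per species.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param times Time grid; default [default_time_grid()] at the shared k_chem.
#' @return List of [timecourse()] objects (3 species x n_replicates).
#' @export
simulate_variant_set <- function(truths, conditions = assay_conditions(),
                                 noise_sd = 0, n_replicates = 1, seed = NULL,
                                 times = NULL) {
  need <- c("ATP", "ADP", "AMP")
  if (!all(need %in% names(truths)))
    stop("`truths` must contain elements ATP, ADP and AMP")
  truths <- truths[need]
  ids <- vapply(truths, function(x) x$variant_id, character(1))
  if (length(unique(ids)) != 1)
    stop("all three species must share one variant_id")
  ks <- vapply(truths, function(x) x$k_chem, numeric(1))
  if (diff(range(ks)) > 1e-12 * mean(ks))
    stop("conservation violated: species must share one k_chem")
  tol <- 1e-8
  if (abs(truths$ATP$n_frac - truths$ADP$n_frac - truths$AMP$n_frac) > tol)
    stop("conservation violated: n_frac(ATP) != n_frac(ADP) + n_frac(AMP)")
  if (abs(truths$ATP$k_cat - truths$ADP$k_cat - truths$AMP$k_cat) > tol)
    stop("conservation violated: k_cat(ATP) != k_cat(ADP) + k_cat(AMP)")
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  if (is.null(times)) times <- default_time_grid(truths$ATP$k_chem)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (rep in seq_len(n_replicates)) {
    for (sp in need) {
      out[[length(out) + 1]] <- simulate_timecourse(
        truths[[sp]], times = times, noise_sd = noise_sd, seed = NULL,
        replicate = rep, conditions = conditions)
    }
  }
  out
}

VALID_CODINGS <- c("wt01", "mut01", "effect_pm1")

#' Ground truth for a 2x2 factorial free-energy dataset
#'
#' Holds the regression coefficients (under a declared predictor coding)
#' from which a factorial dataset of activation free energies is generated,
#' along with the replicate structure and noise level.
#'
#' @param beta0,beta_H,beta_K,beta_HK Intercept, HVGH and KMSKS main effects
#'   and their interaction, kcal/mol, under `coding`.
#' @param coding Predictor coding: "wt01" (1 = native signature present),
#'   "mut01" (1 = mutated), or "effect_pm1" (+1 native / -1 mutant).
#' @param noise_sd Gaussian noise sd on the free-energy scale, kcal/mol.
#' @param n_replicates Replicates per variant combination; >= 1.
#' @param temperature Kelvin, used to emit implied rates.
#' @return An object of class `factorial_truth`.
#' @export
factorial_truth <- function(beta0 = 0, beta_H = 0, beta_K = 0, beta_HK = 0,
                            coding = "wt01", noise_sd = 0, n_replicates = 1,
                            temperature = 310.15) {
  coding <- match.arg(coding, VALID_CODINGS)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (temperature <= 0) stop("`temperature` must be positive (kelvin)")
  structure(
    list(beta0 = beta0, beta_H = beta_H, beta_K = beta_K, beta_HK = beta_HK,
         coding = coding, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates), temperature = temperature),
    class = "factorial_truth"
  )
}

# Numeric predictor value for a wild-type flag under a coding convention
coding_predictor <- function(wt_flag, coding) {
  switch(coding,
         wt01 = as.numeric(wt_flag),
         mut01 = 1 - as.numeric(wt_flag),
         effect_pm1 = 2 * as.numeric(wt_flag) - 1,
         stop("unknown coding: ", coding))
}

# Canonical variant labels for the four corners of the HVGH x KMSKS design
corner_label <- function(hvgh_wt, kmsks_wt) {
  ifelse(hvgh_wt == 1 & kmsks_wt == 1, "WT",
  ifelse(hvgh_wt == 0 & kmsks_wt == 1, "AVGA",
  ifelse(hvgh_wt == 1 & kmsks_wt == 0, "AMSAS", "AVGA_AMSAS")))
}

#' Simulate a complete 2x2 factorial free-energy dataset
#'
#' For each of the four HVGH x KMSKS variant combinations and each
#' replicate, draws an observed activation free energy from the factorial
#' model mean plus Gaussian noise, and also emits the implied rate constant
#' k = exp(-dG / RT) so the pipeline can be driven from rates.
#'
#' @param truth A [factorial_truth()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param reaction Reaction label stored on each row.
#' @return A [factorial_dataset()] (tibble with coding attribute).
#' @examples
#' tr <- factorial_truth(beta0 = 3, beta_HK = 0.36, noise_sd = 0.1,
#'                       n_replicates = 3)
#' simulate_factorial_rates(tr, seed = 1)
#' @export
simulate_factorial_rates <- function(truth, seed = NULL,
                                     reaction = "ACTIVATION_ATP") {
  if (!inherits(truth, "factorial_truth"))
    stop("`truth` must be created by factorial_truth()")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(hvgh_wt = c(0L, 1L), kmsks_wt = c(0L, 1L))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    h <- grid$hvgh_wt[i]; k <- grid$kmsks_wt[i]
    pH <- coding_predictor(h, truth$coding)
    pK <- coding_predictor(k, truth$coding)
    mu <- truth$beta0 + truth$beta_H * pH + truth$beta_K * pK +
      truth$beta_HK * pH * pK
    y <- mu + stats::rnorm(truth$n_replicates, 0, truth$noise_sd)
    tibble::tibble(
      variant_id = corner_label(h, k), hvgh_wt = h, kmsks_wt = k,
      replicate = seq_len(truth$n_replicates), reaction = reaction,
      y_obs = y,
      rate = exp(-y / (R_KCAL * truth$temperature)),
      temperature = truth$temperature)
  })
  factorial_dataset(dplyr::bind_rows(rows), coding = truth$coding)
}
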