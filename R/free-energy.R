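#' Activation free energy from a rate constant
#'
#' Transition-state theory transform `dG = -R T ln(k)` with
#' R = 1.987e-3 kcal/mol/K. Free energies are additive where rates are
#' multiplicative, which is what makes factorial regression on the energy
#' scale meaningful.
#'
#' @param k Rate constant(s), s^-1; must be positive.
#' @param temperature Kelvin. Default 310.15 (37 C).
#' @return Activation free energy, kcal/mol.
#' @examples
#' delta_g_from_rate(1)          # 0
#' delta_g_from_rate(0.001, 310.15)
#' @export
delta_g_from_rate <- function(k, temperature = 310.15) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("rate constants must be positive and finite; a non-positive rate ",
         "signals an unusable fit")
  if (any(temperature <= 0)) stop("`temperature` must be positive (kelvin)")
  -R_KCAL * temperature * log(k)
}

#' Rate constant from an activation free energy
#'
#' Exact inverse of [delta_g_from_rate()].
#'
#' @param delta_g Free energy, kcal/mol.
#' @param temperature Kelvin.
#' @return Rate constant, s^-1.
#' @export
rate_from_delta_g <- function(delta_g, temperature = 310.15) {
  if (any(temperature <= 0)) stop("`temperature` must be positive (kelvin)")
  exp(-delta_g / (R_KCAL * temperature))
}

#' Normalize an acylation rate by the active enzyme fraction
#'
#' Converts a product-formation rate in concentration units (uM/s) to a
#' per-active-enzyme turnover rate (s^-1) by dividing by the active enzyme
#' concentration `n_T * [E]_total`. Burst-derived n_T values put variants
#' with different active fractions on a common footing.
#'
#' @param observed_rate Product formation rate, uM s^-1.
#' @param n_T Active fraction from the ATP burst, in (0, 1].
#' @param cond [assay_conditions()] giving the total enzyme concentration.
#' @return Turnover rate per active enzyme, s^-1.
#' @examples
#' normalize_acylation(0.01, n_T = 0.5, assay_conditions(enzyme_total = 3))
#' @export
normalize_acylation <- function(observed_rate, n_T, cond = assay_conditions()) {
  if (!inherits(cond, "assay_conditions"))
    stop("`cond` must be created by assay_conditions()")
  if (any(n_T <= 0) || any(n_T > 1))
    stop("`n_T` must lie in (0, 1]")
  observed_rate / (n_T * cond$enzyme_total)
}

VALID_REACTIONS <- c("ACTIVATION_ATP", "ACTIVATION_ADP", "ACTIVATION_AMP",
                     "ACYLATION")

#' Free-energy observations from burst fits
#'
#' Converts the first-order rate constant of each converged fit to an
#' activation free energy, one observation per (variant, replicate,
#' species). k_chem is independent of enzyme concentration, so no active-
#' fraction normalization is applied on this path.
#'
#' @param fits List of [fit_burst()] results.
#' @param temperature Kelvin; travels with each observation.
#' @return Tibble with columns variant_id, replicate, reaction, delta_g,
#'   temperature, source_rate.
#' @export
free_energy_observations <- function(fits, temperature = 310.15) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop("no converged fits to transform")
  rows <- lapply(conv, function(f) {
    tibble::tibble(
      variant_id = f$variant_id,
      replicate = f$replicate,
      reaction = paste0("ACTIVATION_", f$species),
      delta_g = delta_g_from_rate(f$k_chem, temperature),
      temperature = temperature,
      source_rate = f$k_chem)
  })
  dplyr::bind_rows(rows)
}
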