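# Gas constant in kcal mol^-1 K^-1
R_KCAL <- 1.987e-3

#' Assay conditions for an active-site titration experiment
#'
#' Bundles the concentrations and temperature under which a single-turnover
#' (burst) time course was collected. The ATP:enzyme ratio is what scales a
#' fitted burst amplitude (a fraction of total ATP) into an active fraction
#' of enzyme molecules, so these values travel with every time course.
#'
#' @param atp_total Total ATP concentration, micromolar. Default 5.
#' @param enzyme_total Total enzyme concentration, micromolar. Default 3.
#' @param temperature Assay temperature in kelvin. Default 310.15 (37 C);
#'   use ~273.65 for on-ice assays.
#' @return An object of class `assay_conditions`.
#' @examples
#' assay_conditions(atp_total = 5, enzyme_total = 3)
#' @export
assay_conditions <- function(atp_total = 5, enzyme_total = 3,
                             temperature = 310.15) {
  if (!is.numeric(atp_total) || length(atp_total) != 1 || atp_total <= 0)
    stop("`atp_total` must be a single positive concentration (uM)")
  if (!is.numeric(enzyme_total) || length(enzyme_total) != 1 || enzyme_total <= 0)
    stop("`enzyme_total` must be a single positive concentration (uM)")
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("`temperature` must be a single positive value in kelvin")
  structure(
    list(atp_total = atp_total, enzyme_total = enzyme_total,
         temperature = temperature, gas_constant = R_KCAL),
    class = "assay_conditions"
  )
}

#' @export
print.assay_conditions <- function(x, ...) {
  cat(sprintf("Assay conditions: [ATP] = %g uM, [Enzyme] = %g uM, T = %g K\n",
              x$atp_total, x$enzyme_total, x$temperature))
  invisible(x)
}

VALID_SPECIES <- c("ATP", "ADP", "AMP", "AA_TRNA")

# ATP is consumed (decay); every product species appears (rise)
species_direction <- function(species) {
  if (species == "ATP") "decay" else "rise"
}

#' A single-turnover time course
#'
#' One signal trajectory -- the fraction of total lane counts in one
#' nucleotide species (or in acyl-tRNA) as a function of time -- for one
#' enzyme variant and replicate.
#'
#' @param variant_id Variant label.
#' @param replicate Replicate index (integer).
#' @param species One of "ATP", "ADP", "AMP", "AA_TRNA".
#' @param seconds Strictly increasing time vector, seconds; at least 5 points.
#' @param fraction Signal vector (fraction of total ATP), same length.
#' @param conditions An [assay_conditions()] object.
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(variant_id, replicate, species, seconds, fraction,
                       conditions = assay_conditions()) {
  species <- match.arg(species, VALID_SPECIES)
  if (!inherits(conditions, "assay_conditions"))
    stop("`conditions` must be created by assay_conditions()")
  seconds <- as.numeric(seconds)
  fraction <- as.numeric(fraction)
  if (length(seconds) != length(fraction))
    stop("`seconds` and `fraction` must have equal length")
  if (length(seconds) < 5)
    stop("a time course needs at least 5 points")
  if (any(diff(seconds) <= 0))
    stop("`seconds` must be strictly increasing")
  if (anyNA(seconds) || anyNA(fraction))
    stop("`seconds` and `fraction` must not contain NA")
  structure(
    list(variant_id = as.character(variant_id),
         replicate = as.integer(replicate),
         species = species,
         seconds = seconds,
         fraction = fraction,
         conditions = conditions),
    class = "timecourse"
  )
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Time course: variant %s, replicate %d, species %s (%d points, %g-%g s)\n",
              x$variant_id, x$replicate, x$species, length(x$seconds),
              min(x$seconds), max(x$seconds)))
  invisible(x)
}
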