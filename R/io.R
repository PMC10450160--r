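#' Write time courses to a long-format CSV plus metadata sidecar
#'
#' The table has one row per (variant, replicate, species, time) with
#' columns `variant_id, replicate, species, seconds, fraction`; the sidecar
#' is YAML carrying the assay conditions (enzyme_uM, atp_uM, temperature_K)
#' and optional variant flags. The same schema is accepted for real data.
#'
#' @param tcs List of [timecourse()] objects.
#' @param path CSV output path.
#' @param meta_path YAML sidecar output path.
#' @param variant_flags Optional data frame (variant_id, hvgh_wt, kmsks_wt)
#'   stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tcs, path, meta_path, variant_flags = NULL) {
  if (!length(tcs)) stop("`tcs` is empty")
  tab <- dplyr::bind_rows(lapply(tcs, function(tc) {
    tibble::tibble(variant_id = tc$variant_id, replicate = tc$replicate,
                   species = tc$species, seconds = tc$seconds,
                   fraction = tc$fraction)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  cond <- tcs[[1]]$conditions
  meta <- list(enzyme_uM = cond$enzyme_total, atp_uM = cond$atp_total,
               temperature_K = cond$temperature)
  if (!is.null(variant_flags))
    meta$variants <- lapply(seq_len(nrow(variant_flags)), function(i)
      as.list(variant_flags[i, ]))
  yaml::write_yaml(meta, meta_path)
  invisible(path)
}

#' Read time courses from a long-format CSV plus metadata sidecar
#'
#' Validates the schema written by [write_timecourses()] and reconstructs
#' one [timecourse()] per distinct (variant, replicate, species). Malformed
#' rows are reported with their row numbers and offending column.
#'
#' @param path CSV input path.
#' @param meta_path YAML sidecar path.
#' @return List with `timecourses` (list of [timecourse()]),
#'   `conditions` ([assay_conditions()]) and `variant_flags` (tibble or
#'   NULL).
#' @export
read_timecourses <- function(path, meta_path) {
  if (!file.exists(path)) stop("input table not found: ", path)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("variant_id", "replicate", "species", "seconds", "fraction")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("replicate", "seconds", "fraction")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric value in column `", col, "` at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    raw[[col]] <- vals
  }
  bad_sp <- which(!raw$species %in% VALID_SPECIES)
  if (length(bad_sp))
    stop("unknown species label at data row(s): ",
         paste(utils::head(bad_sp, 5), collapse = ", "),
         " (expected ", paste(VALID_SPECIES, collapse = "/"), ")")
  meta <- yaml::read_yaml(meta_path)
  for (fld in c("enzyme_uM", "atp_uM", "temperature_K"))
    if (is.null(meta[[fld]])) stop("metadata sidecar lacks field: ", fld)
  cond <- assay_conditions(atp_total = meta$atp_uM,
                           enzyme_total = meta$enzyme_uM,
                           temperature = meta$temperature_K)
  key <- paste(raw$variant_id, raw$replicate, raw$species, sep = "\r")
  tcs <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    idx <- idx[order(raw$seconds[idx])]
    timecourse(raw$variant_id[idx[1]], raw$replicate[idx[1]],
               raw$species[idx[1]], raw$seconds[idx], raw$fraction[idx],
               conditions = cond)
  })
  names(tcs) <- NULL
  flags <- NULL
  if (!is.null(meta$variants))
    flags <- dplyr::bind_rows(lapply(meta$variants, tibble::as_tibble))
  list(timecourses = tcs, conditions = cond, variant_flags = flags)
}

# Tabular summary of burst fits, one row per fit
fits_table <- function(fits) {
  dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      variant_id = f$variant_id, replicate = f$replicate,
      species = f$species, direction = f$direction,
      A = f$A, k_chem = f$k_chem, k_cat = f$k_cat, C = f$C,
      se_A = f$standard_errors[["A"]], se_k_chem = f$standard_errors[["k_chem"]],
      se_k_cat = f$standard_errors[["k_cat"]], se_C = f$standard_errors[["C"]],
      r_squared = f$r_squared, converged = f$converged)
  }))
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: simulate (or read) single-turnover time courses for
#' a 2x2 variant panel, fit the burst model to every curve, aggregate
#' n-values per variant, convert first-order rates to activation free
#' energies, fit the factorial cycle regression, and run the n-value
#' additivity check. Deterministic given the seed; all stage tables plus a
#' JSON summary are written when `out_dir` is set.
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `variants` — list of lists, each with `id`, `hvgh_wt`, `kmsks_wt`,
#'   `n_D`, `n_M`, `k_chem` and optionally `k_cat` (simulation truth), or
#'   `input`/`meta` paths to read measured data; `noise_sd`; `n_replicates`;
#'   `seed`; `coding`; `conditions` (list: atp_uM, enzyme_uM,
#'   temperature_K); optional `out_dir`.
#' @param quiet Suppress progress messages.
#' @return List of class `pipeline_report`: fits and n-value tables,
#'   free-energy observations, `cycle_fit`, `cycle_view`, additivity
#'   regression, convergence log.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  coding <- match.arg(config$coding %||% "wt01", VALID_CODINGS)
  cond_cfg <- config$conditions %||% list()
  cond <- assay_conditions(
    atp_total = cond_cfg$atp_uM %||% 5,
    enzyme_total = cond_cfg$enzyme_uM %||% 3,
    temperature = cond_cfg$temperature_K %||% 310.15)

  if (!is.null(config$input)) {
    say("reading time courses from %s", config$input)
    loaded <- read_timecourses(config$input, config$meta)
    tcs <- loaded$timecourses
    cond <- loaded$conditions
    flags <- loaded$variant_flags
    if (is.null(flags)) stop("metadata sidecar must carry variant flags")
  } else {
    if (is.null(config$variants)) stop("config needs `variants` or `input`")
    if (!is.null(config$seed)) set.seed(config$seed)
    else if ((config$noise_sd %||% 0) > 0)
      stop("a seed is required when simulation noise is requested")
    say("simulating %d variants (noise sd %g, %d replicate(s))",
        length(config$variants), config$noise_sd %||% 0,
        config$n_replicates %||% 1)
    tcs <- list()
    flags <- dplyr::bind_rows(lapply(config$variants, function(v)
      tibble::tibble(variant_id = v$id, hvgh_wt = v$hvgh_wt,
                     kmsks_wt = v$kmsks_wt)))
    for (v in config$variants) {
      truths <- variant_truth(v$id, n_D = v$n_D, n_M = v$n_M,
                              k_chem = v$k_chem, k_cat = v$k_cat %||% 0)
      tcs <- c(tcs, simulate_variant_set(
        truths, conditions = cond, noise_sd = config$noise_sd %||% 0,
        n_replicates = config$n_replicates %||% 1, seed = NULL))
    }
  }

  say("fitting burst model to %d time courses", length(tcs))
  fits <- lapply(tcs, fit_burst)
  n_conv <- sum(vapply(fits, function(f) f$converged, logical(1)))
  say("converged: %d / %d fits", n_conv, length(fits))

  by_variant <- split(fits, vapply(fits, function(f) f$variant_id,
                                   character(1)))
  nsets <- lapply(by_variant, aggregate_n, cond = cond)
  ntab <- dplyr::bind_rows(lapply(nsets, function(s)
    tibble::tibble(variant_id = s$variant_id, n_T = s$n_T, n_D = s$n_D,
                   n_M = s$n_M)))

  obs <- free_energy_observations(fits, temperature = cond$temperature)
  obs <- dplyr::left_join(obs, flags, by = "variant_id")

  atp_obs <- obs[obs$reaction == "ACTIVATION_ATP", ]
  atp_obs$y_obs <- atp_obs$delta_g
  cyc <- fit_cycle(factorial_dataset(atp_obs, coding = coding))
  view <- cycle_view(cyc)
  addit <- additivity_regression(ntab)
  say("additivity slope %.4f; coupling %.4f kcal/mol",
      addit$slope, view$coupling)

  report <- structure(
    list(fits = fits_table(fits), n_values = ntab, observations = obs,
         cycle_fit = cyc, cycle_view = view, additivity = addit,
         conditions = cond, coding = coding,
         convergence = list(converged = n_conv, total = length(fits))),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, name)
      utils::write.csv(tab, file.path(config$out_dir, name), row.names = FALSE)
    wr(report$fits, "fits.csv")
    wr(report$n_values, "nvalues.csv")
    wr(report$observations, "observations.csv")
    wr(cyc$coefficients, "coefficients.csv")
    wr(tibble::tibble(corner = names(view$corners), delta_g = view$corners),
       "corners.csv")
    wr(tibble::tibble(edge = names(view$edges), delta_g = view$edges),
       "edges.csv")
    summary <- list(
      coding = coding,
      coefficients = stats::setNames(as.list(coef(cyc)),
                                     cyc$coefficients$term),
      coupling_kcal_mol = view$coupling,
      additivity = addit[c("slope", "intercept", "r_squared")],
      convergence = report$convergence)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    say("wrote outputs to %s", config$out_dir)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d/%d fits converged, coding %s\n",
              x$convergence$converged, x$convergence$total, x$coding))
  print(x$cycle_view)
  cat(sprintf("n-value additivity: slope %.4f, intercept %.4f, R2 %.4f\n",
              x$additivity$slope, x$additivity$intercept,
              x$additivity$r_squared))
  invisible(x)
}
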