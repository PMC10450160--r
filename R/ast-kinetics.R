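#' Fit the exponential-burst + linear model to a time course
#'
#' Fits `fraction = A * exp(-k_chem * t) + b * t + C` by unweighted
#' Levenberg-Marquardt least squares, where the linear slope `b` carries the
#' steady-state rate: `k_cat = -b` for decay curves (ATP consumption) and
#' `k_cat = +b` for rise curves (product appearance), whose amplitude is
#' negative (`A = -n`, `C = n`) under this shared parameterization.
#'
#' Starting values exploit the model being conditionally linear in (A, b, C):
#' k_cat is seeded from the slope of the last third of points, k_chem from a
#' log-linear fit to the baseline-subtracted burst segment, then A, b, C by
#' linear profiling at that rate. Optimizer failure is reported as
#' `converged = FALSE`, never as an error.
#'
#' @param tc A [timecourse()] object.
#' @return An object of class `burst_fit` with elements `A`, `k_chem`,
#'   `k_cat`, `C`, `standard_errors`, `r_squared`, `residuals`, `direction`,
#'   `converged`.
#' @examples
#' tk <- true_kinetics("WT", "ATP", n_frac = 0.5, k_chem = 0.01, k_cat = 1e-4)
#' fit_burst(simulate_timecourse(tk))
#' @export
fit_burst <- function(tc) {
  if (!inherits(tc, "timecourse"))
    stop("`tc` must be created by timecourse()")
  t <- tc$seconds
  y <- tc$fraction
  if (length(t) < 5)
    stop("too few points: need more observations than parameters")
  if (stats::sd(y) == 0)
    stop("all-constant signal: burst model is unidentifiable")
  direction <- species_direction(tc$species)

  failed <- function() {
    structure(
      list(variant_id = tc$variant_id, replicate = tc$replicate,
           species = tc$species, direction = direction,
           A = NA_real_, k_chem = NA_real_, k_cat = NA_real_, C = NA_real_,
           standard_errors = c(A = NA_real_, k_chem = NA_real_,
                               k_cat = NA_real_, C = NA_real_),
           r_squared = NA_real_, residuals = rep(NA_real_, length(y)),
           converged = FALSE),
      class = "burst_fit")
  }

  starts <- burst_starts(t, y, direction)
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-k * t) + b * t + C,
        start = st,
        lower = c(A = -Inf, k = 1e-12, b = -Inf, C = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(failed())

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 4), names(cf)))
  res <- y - stats::predict(fit)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  k_cat <- if (direction == "decay") -cf[["b"]] else cf[["b"]]
  structure(
    list(variant_id = tc$variant_id, replicate = tc$replicate,
         species = tc$species, direction = direction,
         A = cf[["A"]], k_chem = cf[["k"]], k_cat = k_cat, C = cf[["C"]],
         standard_errors = c(A = se[["A"]], k_chem = se[["k"]],
                             k_cat = se[["b"]], C = se[["C"]]),
         r_squared = 1 - rss / tss,
         residuals = res,
         converged = cf[["k"]] > 0),
    class = "burst_fit")
}

# Starting values for the burst fit; returns a list of candidate start sets,
# best guess first, then coarse fallbacks spanning the observable rate range.
burst_starts <- function(t, y, direction) {
  n <- length(t)
  tail_idx <- seq.int(max(1L, n - ceiling(n / 3) + 1L), n)
  tail_fit <- stats::lm(y[tail_idx] ~ t[tail_idx])
  b0 <- unname(stats::coef(tail_fit)[2])
  base <- stats::coef(tail_fit)[1] + b0 * t
  excess <- y - base  # ~ A * exp(-k t)
  sgn <- if (direction == "decay") 1 else -1
  head_idx <- seq_len(ceiling(n / 2))
  use <- head_idx[sgn * excess[head_idx] > 1e-10]
  k0 <- NA_real_
  if (length(use) >= 3) {
    lf <- stats::lm(log(sgn * excess[use]) ~ t[use])
    k0 <- -unname(stats::coef(lf)[2])
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- 2 / stats::median(t)
  profile_start <- function(k) {
    ex <- exp(-k * t)
    lin <- stats::lm(y ~ ex + t)
    cc <- stats::coef(lin)
    list(A = unname(cc["ex"]), k = k, b = unname(cc["t"]),
         C = unname(cc["(Intercept)"]))
  }
  ks <- unique(c(k0, k0 * c(0.2, 5), 1 / max(t) * c(3, 30)))
  lapply(ks, profile_start)
}

#' @export
print.burst_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Burst fit (%s/%s rep %d): NOT CONVERGED\n",
                x$variant_id, x$species, x$replicate))
    return(invisible(x))
  }
  cat(sprintf(
    "Burst fit (%s/%s rep %d, %s): A = %.4g, k_chem = %.4g /s, k_cat = %.4g /s, C = %.4g (R2 = %.4f)\n",
    x$variant_id, x$species, x$replicate, x$direction,
    x$A, x$k_chem, x$k_cat, x$C, x$r_squared))
  invisible(x)
}

#' Active-fraction (n-value) estimators from a burst fit
#'
#' The burst amplitude, expressed as a fraction of total ATP, counts active
#' enzyme molecules once scaled by the ATP:enzyme ratio. Two estimators are
#' available from each fit. Decay curves: `n = A * [ATP]/[E]` and
#' `n = (1 - C) * [ATP]/[E]`. Rise curves: the offset carries the burst, so
#' `n = C * [ATP]/[E]` is canonical; the amplitude-based companion is
#' `|A| * [ATP]/[E]` by default (the rise amplitude is negative under the
#' shared parameterization), with `(1 - A) * [ATP]/[E]` available under
#' `rise_a_convention = "one_minus"` since both conventions circulate and
#' neither is silently preferred.
#'
#' @param fit A converged [fit_burst()] result.
#' @param cond [assay_conditions()] giving the two concentrations.
#' @param rise_a_convention "abs" (default) or "one_minus"; only affects
#'   rise-curve `n_from_A`.
#' @return Named numeric vector `c(n_from_A, n_from_C)`.
#' @examples
#' tk <- true_kinetics("WT", "ATP", n_frac = 0.4, k_chem = 0.02)
#' n_values(fit_burst(simulate_timecourse(tk)), assay_conditions(5, 3))
#' @export
n_values <- function(fit, cond = assay_conditions(),
                     rise_a_convention = c("abs", "one_minus")) {
  rise_a_convention <- match.arg(rise_a_convention)
  if (!inherits(fit, "burst_fit")) stop("`fit` must come from fit_burst()")
  if (!isTRUE(fit$converged)) stop("n-values require a converged fit")
  if (!inherits(cond, "assay_conditions"))
    stop("`cond` must be created by assay_conditions()")
  ratio <- cond$atp_total / cond$enzyme_total
  if (fit$direction == "decay") {
    c(n_from_A = fit$A * ratio, n_from_C = (1 - fit$C) * ratio)
  } else {
    n_A <- if (rise_a_convention == "abs") abs(fit$A) * ratio
           else (1 - fit$A) * ratio
    c(n_from_A = n_A, n_from_C = fit$C * ratio)
  }
}

#' Aggregate n-values across replicates and estimators for one variant
#'
#' Pools both n-value estimators over all converged replicate fits of each
#' species and reports the per-species mean and sample standard deviation.
#' `n_T`, `n_D` and `n_M` are the means for ATP, ADP and AMP; non-converged
#' fits are skipped (and counted).
#'
#' @param fits List of [fit_burst()] results for one variant (any mix of
#'   species and replicates).
#' @param cond [assay_conditions()].
#' @param rise_a_convention Passed to [n_values()].
#' @return An object of class `n_value_set`: the variant id, a per-species
#'   tibble (mean of each estimator, pooled mean, sd, fit counts) and the
#'   scalars `n_T`, `n_D`, `n_M`.
#' @export
aggregate_n <- function(fits, cond = assay_conditions(),
                        rise_a_convention = c("abs", "one_minus")) {
  rise_a_convention <- match.arg(rise_a_convention)
  if (!length(fits)) stop("`fits` is empty")
  ids <- unique(vapply(fits, function(f) f$variant_id, character(1)))
  if (length(ids) != 1) stop("`fits` must all belong to one variant")
  species <- unique(vapply(fits, function(f) f$species, character(1)))
  rows <- lapply(species, function(sp) {
    sp_fits <- Filter(function(f) f$species == sp, fits)
    conv <- Filter(function(f) isTRUE(f$converged), sp_fits)
    if (!length(conv))
      stop("no converged fits for species ", sp, " of variant ", ids)
    nv <- vapply(conv, n_values, numeric(2), cond = cond,
                 rise_a_convention = rise_a_convention)
    pooled <- c(nv["n_from_A", ], nv["n_from_C", ])
    tibble::tibble(
      species = sp,
      n_from_A = mean(nv["n_from_A", ]),
      n_from_C = mean(nv["n_from_C", ]),
      n_mean = mean(pooled),
      n_sd = if (length(pooled) > 1) stats::sd(pooled) else NA_real_,
      n_fits = length(conv),
      n_skipped = length(sp_fits) - length(conv))
  })
  tab <- dplyr::bind_rows(rows)
  get_mean <- function(sp) {
    i <- match(sp, tab$species)
    if (is.na(i)) NA_real_ else tab$n_mean[i]
  }
  structure(
    list(variant_id = ids, species = tab,
         n_T = get_mean("ATP"), n_D = get_mean("ADP"), n_M = get_mean("AMP")),
    class = "n_value_set")
}

#' @export
print.n_value_set <- function(x, ...) {
  cat(sprintf("n-values for variant %s: n_T = %.3f, n_D = %.3f, n_M = %.3f\n",
              x$variant_id, x$n_T, x$n_D, x$n_M))
  print(x$species)
  invisible(x)
}
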