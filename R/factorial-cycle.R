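#' Assemble a 2x2 factorial free-energy dataset
#'
#' Validates and tags a long table of replicate free-energy observations for
#' the four HVGH x KMSKS variant combinations. The coding attribute declares
#' how the wild-type flags map to regression predictors; it changes the
#' meaning (and scale) of main-effect and interaction coefficients, but
#' never the fitted corner energies.
#'
#' @param data Data frame with columns `hvgh_wt`, `kmsks_wt` (0/1 flags),
#'   `y_obs` (kcal/mol), and optionally `variant_id`, `replicate`,
#'   `reaction`.
#' @param coding "wt01" (default; predictor 1 = native signature present),
#'   "mut01", or "effect_pm1".
#' @return A tibble of class `factorial_dataset` with a `coding` attribute.
#' @export
factorial_dataset <- function(data, coding = "wt01") {
  coding <- match.arg(coding, VALID_CODINGS)
  need <- c("hvgh_wt", "kmsks_wt", "y_obs")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(data$hvgh_wt %in% c(0, 1)) || !all(data$kmsks_wt %in% c(0, 1)))
    stop("`hvgh_wt` and `kmsks_wt` must be 0/1 flags")
  if (any(!is.finite(data$y_obs)))
    stop("`y_obs` must be finite")
  combos <- unique(paste(data$hvgh_wt, data$kmsks_wt))
  all4 <- c("0 0", "1 0", "0 1", "1 1")
  absent <- setdiff(all4, combos)
  if (length(absent))
    stop("missing variant combination(s) (hvgh_wt kmsks_wt): ",
         paste(absent, collapse = "; "))
  out <- tibble::as_tibble(data)
  if (!"variant_id" %in% names(out))
    out$variant_id <- corner_label(out$hvgh_wt, out$kmsks_wt)
  attr(out, "coding") <- coding
  class(out) <- c("factorial_dataset", class(out))
  out
}

coding_of <- function(data) {
  cd <- attr(data, "coding")
  if (is.null(cd)) "wt01" else cd
}

# Saturated design matrix (1, pH, pK, pH*pK) at the four corners, in fixed
# corner order (0,0), (1,0), (0,1), (1,1) of the wild-type flags.
corner_design <- function(coding) {
  h <- c(0, 1, 0, 1); k <- c(0, 0, 1, 1)
  pH <- coding_predictor(h, coding)
  pK <- coding_predictor(k, coding)
  m <- cbind(1, pH, pK, pH * pK)
  dimnames(m) <- list(c("double", "H_wt", "K_wt", "WT"),
                      c("beta0", "beta_H", "beta_K", "beta_HK"))
  m
}

#' Fit the factorial regression for a thermodynamic cycle
#'
#' Ordinary least squares of the observed free energies on the two signature
#' predictors and their interaction, `y = b0 + bH*pH + bK*pK + bHK*pH*pK`,
#' treating replicates as independent observations. Standard errors, t and
#' two-sided p values come from the replicate error; internally studentized
#' residuals support the outlier screen. With one observation per corner the
#' model is saturated: coefficients are exact and inference is unavailable.
#'
#' @param data A [factorial_dataset()] (or data frame acceptable to it).
#' @param coding Overrides the dataset's coding attribute if given.
#' @return An object of class `cycle_fit`: coefficient table (estimate, SE,
#'   t, p), covariance matrix, residuals, studentized residuals, R-squared,
#'   coding.
#' @examples
#' d <- simulate_factorial_rates(
#'   factorial_truth(beta_H = 0.45, beta_K = -0.32, beta_HK = 0.36,
#'                   noise_sd = 0.1, n_replicates = 3), seed = 1)
#' fit_cycle(d)
#' @export
fit_cycle <- function(data, coding = NULL) {
  if (!inherits(data, "factorial_dataset"))
    data <- factorial_dataset(data, coding = coding %||% "wt01")
  coding <- coding %||% coding_of(data)
  coding <- match.arg(coding, VALID_CODINGS)
  pH <- coding_predictor(data$hvgh_wt, coding)
  pK <- coding_predictor(data$kmsks_wt, coding)
  y <- data$y_obs
  fit <- stats::lm(y ~ pH * pK)
  cf <- stats::coef(fit)
  names(cf) <- c("beta0", "beta_H", "beta_K", "beta_HK")
  # saturated or noiseless designs legitimately fit perfectly; the summary
  # warning for that case is expected, not a defect
  sm <- suppressWarnings(summary(fit))
  full <- matrix(NA_real_, 4, 3,
                 dimnames = list(names(cf), c("se", "t", "p")))
  full[seq_len(nrow(sm$coefficients)), ] <- sm$coefficients[, 2:4]
  vc <- suppressWarnings(stats::vcov(fit))
  dimnames(vc) <- list(names(cf), names(cf))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) NA_real_ else sm$r.squared
  stud <- if (stats::df.residual(fit) > 1)
    stats::rstandard(fit) else rep(NA_real_, length(y))
  structure(
    list(coefficients = tibble::tibble(
           term = names(cf), estimate = unname(cf),
           se = full[, "se"], t = full[, "t"], p = full[, "p"]),
         vcov = vc,
         residuals = unname(stats::residuals(fit)),
         studentized_residuals = unname(stud),
         r_squared = r2,
         df_residual = stats::df.residual(fit),
         n_obs = length(y),
         coding = coding),
    class = "cycle_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cycle_fit <- function(x, ...) {
  cat(sprintf("Thermodynamic-cycle regression (%s coding, %d obs, R2 = %s)\n",
              x$coding, x$n_obs,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  print(x$coefficients)
  invisible(x)
}

#' Extract coefficient estimates from a cycle fit
#'
#' @param object A `cycle_fit`.
#' @param ... Ignored.
#' @return Named numeric vector (beta0, beta_H, beta_K, beta_HK).
#' @export
coef.cycle_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' 95% confidence intervals for cycle-fit coefficients
#'
#' Replicate-error t intervals on each coefficient.
#'
#' @param object A `cycle_fit`.
#' @param parm Coefficient names (default all).
#' @param level Confidence level.
#' @param ... Ignored.
#' @return Matrix with lower and upper bounds.
#' @export
confint.cycle_fit <- function(object, parm = NULL, level = 0.95, ...) {
  est <- coef(object)
  se <- object$coefficients$se
  if (object$df_residual < 1)
    stop("no residual degrees of freedom: intervals unavailable")
  tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  out <- cbind(lower = est - tq * se, upper = est + tq * se)
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Corner free energies implied by a cycle fit
#'
#' Fitted cell means at the four variant combinations, named by corner:
#' `WT` (both native), `AVGA` (HVGH mutated), `AMSAS` (KMSKS mutated),
#' `AVGA_AMSAS` (double mutant). These are invariant to the coding.
#'
#' @param fit A `cycle_fit`.
#' @return Named numeric vector of four corner energies, kcal/mol.
#' @export
cycle_corners <- function(fit) {
  X <- corner_design(fit$coding)
  mu <- as.numeric(X %*% coef(fit))
  stats::setNames(mu[c(4, 2, 3, 1)], c("WT", "AMSAS", "AVGA", "AVGA_AMSAS"))[
    c("WT", "AVGA", "AMSAS", "AVGA_AMSAS")]
}

#' Double-mutant-cycle coupling free energy from corner energies
#'
#' Classic mutant-cycle arithmetic:
#' `coupling = dG(WT) - dG(AVGA) - dG(AMSAS) + dG(double)`. A negative value
#' means the two signatures stabilize the transition state cooperatively
#' (favourable coupling); a positive value means they work against one
#' another. Under wt01 coding this equals the fitted interaction
#' coefficient exactly.
#'
#' @param corners Named numeric vector with elements `WT`, `AVGA`, `AMSAS`,
#'   `AVGA_AMSAS` (kcal/mol), e.g. from [cycle_corners()].
#' @return Coupling free energy, kcal/mol.
#' @examples
#' double_mutant_coupling(c(WT = 0.49, AVGA = -0.32, AMSAS = 0.45,
#'                          AVGA_AMSAS = 0))
#' @export
double_mutant_coupling <- function(corners) {
  need <- c("WT", "AVGA", "AMSAS", "AVGA_AMSAS")
  if (!all(need %in% names(corners)))
    stop("`corners` must name WT, AVGA, AMSAS and AVGA_AMSAS")
  if (any(!is.finite(corners[need]))) stop("corner energies must be finite")
  unname(corners["WT"] - corners["AVGA"] - corners["AMSAS"] +
           corners["AVGA_AMSAS"])
}

#' Re-express a factorial dataset or cycle fit under another coding
#'
#' Predictor codings (wt01, mut01, effect_pm1) are exact linear
#' reparameterizations of the same saturated model: corner predictions are
#' invariant, while individual coefficients change scale and meaning (the
#' effect_pm1 interaction is a quarter of the wt01 one, and main effects
#' shift by interaction terms). For a fit, coefficients and their covariance
#' are transformed exactly; for a dataset, only the coding tag changes
#' because predictors are derived from the stored flags.
#'
#' @param x A `factorial_dataset` or `cycle_fit`.
#' @param coding Target coding.
#' @return Object of the same class under the new coding.
#' @export
recode <- function(x, coding) UseMethod("recode")

#' @export
recode.factorial_dataset <- function(x, coding) {
  coding <- match.arg(coding, VALID_CODINGS)
  attr(x, "coding") <- coding
  x
}

#' @export
recode.cycle_fit <- function(x, coding) {
  coding <- match.arg(coding, VALID_CODINGS)
  if (coding == x$coding) return(x)
  # mu = X_old beta_old = X_new beta_new  =>  beta_new = X_new^-1 X_old beta_old
  M <- solve(corner_design(coding), corner_design(x$coding))
  est <- as.numeric(M %*% coef(x))
  vc <- M %*% x$vcov %*% t(M)
  dimnames(vc) <- dimnames(x$vcov)
  se <- sqrt(diag(vc))
  tval <- est / se
  pval <- if (x$df_residual > 0)
    2 * stats::pt(abs(tval), x$df_residual, lower.tail = FALSE)
  else rep(NA_real_, 4)
  x$coefficients <- tibble::tibble(
    term = x$coefficients$term, estimate = est, se = se, t = tval, p = pval)
  x$vcov <- vc
  x$coding <- coding
  x
}

#' Thermodynamic-cycle view of a factorial fit
#'
#' Arranges the fitted corner energies as a mutant cycle: four corners, four
#' signed edges traversed WT -> AVGA -> double -> AMSAS -> WT (each edge the
#' free-energy change of one mutation step), and the coupling energy. The
#' signed edges telescope to zero around the cycle, and the difference
#' between opposite edges equals the coupling.
#'
#' @param fit A `cycle_fit`.
#' @return An object of class `cycle_view` with `corners`, `edges`,
#'   `coupling`.
#' @export
cycle_view <- function(fit) {
  if (!inherits(fit, "cycle_fit")) stop("`fit` must come from fit_cycle()")
  corners <- cycle_corners(fit)
  edges <- c(
    "WT->AVGA" = unname(corners["AVGA"] - corners["WT"]),
    "AVGA->AVGA_AMSAS" = unname(corners["AVGA_AMSAS"] - corners["AVGA"]),
    "AVGA_AMSAS->AMSAS" = unname(corners["AMSAS"] - corners["AVGA_AMSAS"]),
    "AMSAS->WT" = unname(corners["WT"] - corners["AMSAS"]))
  structure(
    list(corners = corners, edges = edges,
         coupling = double_mutant_coupling(corners)),
    class = "cycle_view")
}

#' @export
print.cycle_view <- function(x, ...) {
  cat("Thermodynamic cycle (kcal/mol)\n corners:\n")
  print(round(x$corners, 4))
  cat(" edges (successive mutation steps):\n")
  print(round(x$edges, 4))
  cat(sprintf(" coupling = %.4f kcal/mol (%s)\n", x$coupling,
              if (x$coupling < 0) "cooperative, favourable"
              else if (x$coupling > 0) "anti-cooperative, unfavourable"
              else "additive"))
  invisible(x)
}

#' Factorial regression for an arbitrary number of two-level factors
#'
#' Generalizes [fit_cycle()] to 2^k designs -- for example adding catalyst
#' identity (urzyme vs full-length enzyme) as a third factor -- by fitting
#' the saturated OLS model with all main effects and interactions of the
#' declared wild-type/native flags under one coding convention.
#'
#' @param data Data frame with one 0/1 flag column per factor and a numeric
#'   response column.
#' @param factors Character vector of flag column names.
#' @param response Response column name, default "y_obs" (kcal/mol).
#' @param coding Predictor coding applied to every factor.
#' @return List with the coefficient table (term, estimate, se, t, p),
#'   `r_squared`, `residuals`, `df_residual` and `coding`. Term names join
#'   factor names with ":" for interactions.
#' @examples
#' d <- expand.grid(hvgh_wt = 0:1, kmsks_wt = 0:1, full_length = 0:1)
#' d$y_obs <- rnorm(8)
#' fit_factorial(d, c("hvgh_wt", "kmsks_wt", "full_length"))
#' @export
fit_factorial <- function(data, factors, response = "y_obs",
                          coding = "wt01") {
  coding <- match.arg(coding, VALID_CODINGS)
  missing_cols <- setdiff(c(factors, response), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (length(factors) < 1) stop("need at least one factor")
  for (f in factors)
    if (!all(data[[f]] %in% c(0, 1)))
      stop("`", f, "` must be a 0/1 flag column")
  combos <- unique(do.call(paste, data[factors]))
  if (length(combos) < 2^length(factors))
    stop("all ", 2^length(factors), " factor combinations must be present")
  preds <- lapply(factors, function(f) coding_predictor(data[[f]], coding))
  names(preds) <- factors
  df <- data.frame(.y = data[[response]], preds, check.names = FALSE)
  form <- stats::as.formula(
    paste(".y ~", paste(sprintf("`%s`", factors), collapse = " * ")))
  fit <- stats::lm(form, data = df)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  terms <- gsub("`", "", rownames(cf))
  terms[terms == "(Intercept)"] <- "intercept"
  tss <- sum((df$.y - mean(df$.y))^2)
  list(coefficients = tibble::tibble(
         term = terms, estimate = cf[, 1], se = cf[, 2],
         t = cf[, 3], p = cf[, 4]),
       r_squared = if (tss == 0) NA_real_ else sm$r.squared,
       residuals = unname(stats::residuals(fit)),
       df_residual = stats::df.residual(fit),
       coding = coding)
}
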