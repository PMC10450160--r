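#' Nucleotide-conservation (additivity) regression of n-values
#'
#' If every consumed ATP appears as either ADP or AMP in the first round,
#' the active fractions must satisfy n_T = n_D + n_M. This fits the simple
#' least-squares regression of n_T on (n_D + n_M) across variants; slope
#' near 1 and intercept near 0 certify mass balance of the burst estimates.
#'
#' @param nsets List of [aggregate_n()] results, or a data frame with
#'   columns `n_T`, `n_D`, `n_M` (one row per variant). At least 3 variants.
#' @return List with `slope`, `intercept`, `r_squared` and the per-variant
#'   table used.
#' @export
additivity_regression <- function(nsets) {
  if (is.data.frame(nsets)) {
    tab <- tibble::as_tibble(nsets)
  } else {
    tab <- dplyr::bind_rows(lapply(nsets, function(s) {
      if (!inherits(s, "n_value_set"))
        stop("`nsets` must contain n_value_set objects or be a data frame")
      tibble::tibble(variant_id = s$variant_id,
                     n_T = s$n_T, n_D = s$n_D, n_M = s$n_M)
    }))
  }
  need <- c("n_T", "n_D", "n_M")
  if (!all(need %in% names(tab)))
    stop("need columns n_T, n_D and n_M")
  tab <- tab[stats::complete.cases(tab[need]), ]
  if (nrow(tab) < 3)
    stop("need at least 3 variants with complete n_T, n_D, n_M")
  x <- tab$n_D + tab$n_M
  if (stats::sd(x) == 0)
    stop("degenerate predictor: n_D + n_M is constant across variants")
  fit <- stats::lm(tab$n_T ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       data = tab)
}

#' Correlation matrix between mutational profiles
#'
#' Compares reactions by the shape of their mutational response: each
#' profile is the vector of non-intercept coefficients (beta_H, beta_K,
#' beta_HK) for one reaction. Pearson r carries the sense (correlated vs
#' anticorrelated); R-squared carries the strength. Both are reported
#' because a profile and its negation are perfectly (anti)correlated with
#' identical R-squared.
#'
#' @param attributions Numeric matrix or data frame, one column per
#'   reaction, rows = the three non-intercept terms; or a named list of
#'   length-3 vectors.
#' @return List with symmetric matrices `r` and `r_squared`.
#' @export
profile_correlations <- function(attributions) {
  if (is.list(attributions) && !is.data.frame(attributions))
    attributions <- do.call(cbind, attributions)
  m <- as.matrix(attributions)
  if (nrow(m) != 3)
    stop("each profile must have exactly the three non-intercept terms")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance profile(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  r <- stats::cor(m)
  list(r = r, r_squared = r^2)
}

#' AMP/ADP product partition for one variant
#'
#' @param nset An [aggregate_n()] result with ADP and AMP entries.
#' @return Tibble row: variant_id, n_D, n_M, m_over_d, pct_adp, pct_amp
#'   (percentages of total ATP consumption appearing as each product).
#' @export
product_partition <- function(nset) {
  if (!inherits(nset, "n_value_set")) stop("`nset` must come from aggregate_n()")
  if (is.na(nset$n_D) || is.na(nset$n_M))
    stop("partition requires both ADP and AMP n-values")
  if (nset$n_D <= 0) stop("zero or negative n_D: M/D ratio undefined")
  tibble::tibble(
    variant_id = nset$variant_id,
    n_D = nset$n_D, n_M = nset$n_M,
    m_over_d = nset$n_M / nset$n_D,
    pct_adp = 100 * nset$n_D / nset$n_T,
    pct_amp = 100 * nset$n_M / nset$n_T)
}

#' Factorial regression of the AMP/ADP partition ratio
#'
#' Applies the same saturated 2x2 regression machinery to the M/D ratio
#' (AMP produced per ADP produced) to attribute the partition to the two
#' signature sequences. The raw ratio is regressed by default, matching the
#' usual phrasing; `log_ratio = TRUE` uses log(M/D), often preferable since
#' ratios are scale-asymmetric.
#'
#' @param partitions Data frame with columns `variant_id` (or `hvgh_wt`,
#'   `kmsks_wt` directly) and `m_over_d`; one or more rows per variant.
#' @param flags Optional data frame mapping `variant_id` to `hvgh_wt`,
#'   `kmsks_wt` when the partitions table lacks the flags.
#' @param log_ratio Regress log(M/D) instead of M/D.
#' @param coding Predictor coding, default wt01.
#' @return A [fit_cycle()] result.
#' @export
partition_regression <- function(partitions, flags = NULL, log_ratio = FALSE,
                                 coding = "wt01") {
  tab <- tibble::as_tibble(partitions)
  if (!"m_over_d" %in% names(tab)) stop("need column m_over_d")
  if (!all(c("hvgh_wt", "kmsks_wt") %in% names(tab))) {
    if (is.null(flags))
      stop("supply hvgh_wt/kmsks_wt columns or a `flags` table")
    tab <- dplyr::left_join(tab, flags, by = "variant_id")
  }
  if (any(tab$m_over_d <= 0) && log_ratio)
    stop("non-positive M/D ratio: log transform undefined")
  tab$y_obs <- if (log_ratio) log(tab$m_over_d) else tab$m_over_d
  fit_cycle(factorial_dataset(tab, coding = coding))
}
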