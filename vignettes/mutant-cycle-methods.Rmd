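---
title: "Burst kinetics and mutant-cycle thermodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst kinetics and mutant-cycle thermodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutcycle)
```

This vignette documents the models behind `mutcycle`, the assumptions they
make, the numerical choices in the fitting code, and the design decisions
taken where more than one convention circulates in the field.

## The single-turnover burst model

Active-site titration (AST) uses substrate-level enzyme so that the first
catalytic round produces a stoichiometric "burst" of product. Every time
course — the fraction of total lane signal in one adenine nucleotide
species, or in acyl-tRNA — is modelled as a first-order burst plus a linear
steady state:

$$P(t) = A\,e^{-k_\mathrm{chem} t} - k_\mathrm{cat}\,t + C$$

* `k_chem` (s⁻¹): the internal first-order rate constant of the burst
  phase. It is independent of enzyme concentration, which is why it can be
  transformed to a free energy without active-fraction normalization.
* `k_cat` (fraction·s⁻¹): the steady-state turnover rate on the fraction
  scale.
* `A`, `C` (fractions): amplitude and offset. For ATP decay the curve
  starts at 1 and `A` is the burst size; for rising product curves the
  roles invert and the signs of the rate terms flip. We parameterize rise
  curves canonically as $P(t) = n(1 - e^{-k_\mathrm{chem}t}) +
  k_\mathrm{cat}t$, which is the same model with $A = -n$, $C = n$. The
  shared four-parameter form lets one fitter serve both directions;
  `fit_burst()` reports `k_cat` with the direction-appropriate sign.

Signals are expressed as fractions of total ATP per lane. This is the only
normalization under which the titration arithmetic
$n = A\,[\mathrm{ATP}]/[\mathrm{E}]$ is dimensionally coherent: the burst
consumes `A` of the ATP pool, i.e. `A·[ATP]` μM of sites, out of `[E]` μM
of enzyme.

### Active-fraction estimators

Each converged fit yields two n-value estimators. Decay:
$n = A\,[\mathrm{ATP}]/[\mathrm{E}]$ and
$n = (1-C)\,[\mathrm{ATP}]/[\mathrm{E}]$; they are identical when the model
fits exactly and differ only through noise. Rise: the offset carries the
burst, $n = C\,[\mathrm{ATP}]/[\mathrm{E}]$. For the amplitude-based rise
companion two conventions circulate: $|A|\,[\mathrm{ATP}]/[\mathrm{E}]$
(the algebraic mirror of the decay estimator, our default) and
$(1-A)\,[\mathrm{ATP}]/[\mathrm{E}]$. The latter is not derivable from the
canonical reparameterization without an additional, unstated normalization
convention, so `n_values()` exposes it only behind the explicit
`rise_a_convention = "one_minus"` flag; neither is silently preferred.
`aggregate_n()` pools both estimators over all converged replicate fits per
species and reports the mean and sample standard deviation (a single value
yields `NA` dispersion, reported as missing rather than zero).

### Numerical choices in the fitter

The model is conditionally linear in `(A, C)` given the rates, which the
initialization exploits: `k_cat` is seeded from the slope of the last third
of points; subtracting that tail line leaves an approximately exponential
excess whose log-linear fit over the first half of points seeds `k_chem`;
`A`, `C` then come from linear profiling at those rates. Full
Levenberg–Marquardt refinement runs with a relative tolerance of 1e-10 on
the residual sum of squares and at most 500 iterations, with `k_chem`
bounded positive. If the refined start fails, a small ladder of alternative
rate starts spanning the observable range is tried. Failure after that is a
*state* (`converged = FALSE`), never an exception: aggregation skips and
counts such fits. Degenerate inputs — fewer than five points, all-constant
signal — are hard errors, since no parameterization is identifiable. Fits
are unweighted (densitometry error is roughly signal-independent at these
exposures) and `r_squared` is $1 - \mathrm{RSS}/\mathrm{TSS}$ about the
mean.

## Free energies

Rates map to activation free energies by $\Delta G^\ddagger = -RT\ln k$
with $R = 1.987\times10^{-3}$ kcal·mol⁻¹·K⁻¹. Temperature is per-dataset
metadata: 310.15 K by default (assays at 37 °C) and 273.65 K for on-ice
datasets — the exact on-ice temperature is configurable because "slightly
above 0 °C" is not a precise statement, and no attempt is made to
temperature-correct on-ice rates to 37 °C. Acylation rates measured in
concentration units are first divided by the active enzyme concentration
$n_T\,[\mathrm{E}]$ (`normalize_acylation()`) so that variants with
different active fractions are compared per functional molecule.
Non-positive rates are loud errors: they signal an unusable fit, and
silently dropping them would bias the factorial design.

## The factorial cycle regression

Replicate free energies for the four variant combinations are fitted by
OLS to $Y = \beta_0 + \beta_H P_H + \beta_K P_K + \beta_{HK} P_H P_K +
\varepsilon$, replicates treated as independent observations (plain
multiple regression, no mixed effects). Standard errors, t statistics and
two-sided p values come from the replicate error; no multiple-testing
correction is applied. Internally studentized residuals support the
outlier screen. A missing corner makes the design rank-deficient and is a
hard error naming the absent combination.

**Coding convention.** The default is wt01: predictor 1 when the native
motif is present, 0 when mutated. This choice makes $\beta_{HK}$ exactly
the classic double-mutant coupling energy
$\Delta G^\ddagger(\mathrm{WT}) - \Delta G^\ddagger(\mathrm{AVGA}) -
\Delta G^\ddagger(\mathrm{AMSAS}) + \Delta G^\ddagger(\mathrm{double})$,
and it makes the worked signature-coefficient example internally
consistent (a +0.45 HVGH main effect plus a +0.36 interaction reproduce
the ≈1 kcal/mol gap — a ≈5-fold rate ratio at 37 °C — between the most and
least active variants). Because lower-order coefficients depend on where
along the interaction they are evaluated, `recode()` converts fits exactly
between wt01, mut01 and ±1 effect coding by the linear map
$\beta' = X'^{-1} X \beta$ on coefficients and $M V M^\top$ on their
covariance; corner predictions are invariant, and the effect-coding
interaction is one quarter of the wt01 one. Every output carries its
coding label.

Error bars on coefficients are reported both as standard errors and as
95% t intervals (`confint()`), since conventions differ between
laboratories.

## Consistency analyses

* `additivity_regression()` fits the *simple* least-squares regression of
  $n_T$ on $n_D + n_M$ across variants. A more elaborate
  simultaneous-equation formulation with separate ADP and AMP coefficients
  exists, but its printed form is ambiguous about the role of the offset
  term, so the simple regression — slope, intercept, R² — is the supported
  contract. At least three variants are required; a constant predictor is
  a degeneracy error.
* `profile_correlations()` compares reactions by the Pearson correlation of
  their non-intercept coefficient vectors $(\beta_H, \beta_K,
  \beta_{HK})$. The sign of r is reported separately from R² because a
  profile and its negation (closely anticorrelated reactions) have
  identical R².
* `partition_regression()` applies the same factorial machinery to the
  AMP/ADP partition ratio M/D. The raw ratio is the default response;
  `log_ratio = TRUE` is offered because ratios are scale-asymmetric, and
  the output flags which was used.

## The synthetic-data generator

The generator exists so that every downstream stage can be validated by
parameter recovery. It emulates:

* exponential-burst + linear time courses evaluated exactly (to machine
  precision) from the declared parameterization;
* nucleotide conservation by construction: `variant_truth()` builds the
  three-species truth with $n_{ATP} = n_{ADP} + n_{AMP}$, a shared
  `k_chem`, and the steady-state rate partitioned between ADP and AMP in
  proportion to their bursts, so ATP loss equals product gain at *every*
  time point, not just in the burst;
* triplicate structure with additive homoscedastic Gaussian noise on the
  fraction scale. The noise model is our choice — the densitometry error
  model is not stated anywhere authoritative — and values are deliberately
  not clipped to [0, 1], preserving the model's linearity so that fits to
  noisy data remain unbiased;
* factorial datasets drawn from declared β coefficients under a declared
  coding, with the implied rates $k = e^{-\Delta G^\ddagger/RT}$ emitted
  alongside.

The default sampling grid is 16 points: 12 near-geometric times from
0.1/k_chem to 5/k_chem resolving the burst, plus a 4-point linear tail to
12/k_chem resolving the steady state.

It does **not** emulate TLC imaging artifacts, heteroscedastic or
correlated noise, baseline drift, the mechanism producing ADP (e.g.
adenylate rephosphorylation), or lane-loading variation. Passing recovery
tests therefore certify the *estimation machinery* — not robustness to
every pathology of real densitometry data.

## Precision limits of the additivity check

One property deserves an honest caveat. With four variants whose active
fractions span only 0.60–0.70 and per-point noise of sd 0.01, the burst
fitter's amplitude precision is already at the information-theoretic limit
(the Cramér–Rao bound gives sd(A) ≈ 0.012 for the 16-point grid, and the
fitter attains it). The per-variant n-value error after pooling two
estimators and three replicates is then ≈0.01, comparable to the spread of
the predictor, so the fitted additivity *slope* has a sampling standard
deviation of roughly 0.2–0.3 under these conditions: individual panels
scatter well beyond a few percent around 1 even though the estimates are
unbiased and each variant satisfies $n_T \approx n_D + n_M$ to a couple of
percent. Tight slope recovery should be expected only with more variants, a
wider active-fraction range, or lower noise; the per-variant conservation
identity is the sharper diagnostic at this design size.

## Problem sizes used by the test suite

The suite validates: zero-noise identifiability (relative error ≤ 1e-6 on
all four burst parameters); optimizer-vs-grid-search equivalence on 20
noisy instances; OLS-vs-contrast equality on 1,000 random saturated
tables at 1e-10; 95% CI coverage of the interaction coefficient over 500
simulated triplicate datasets (expected band 0.92–0.98); cycle closure to
1e-12; and an end-to-end four-variant AST panel at noise sd 0.01. These
sizes keep the default run to tens of seconds while leaving Monte-Carlo
error well below the tolerances tested.

## Known limitations

* No global multi-species fitting with shared `k_chem`: species are fitted
  independently, as is standard for this assay.
* No mixed-effects treatment of replicates; day effects are not modelled.
* `fit_factorial()` extends the same linear-model route to 2³ (and higher)
  designs — e.g. catalyst identity as a third factor — but the cycle-view
  and recoding conveniences target the two-factor case.
* Temperature correction across datasets measured at different
  temperatures is deliberately out of scope; observations carry their
  temperature and are only ever compared within a dataset.
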