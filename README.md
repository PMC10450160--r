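# mutcycle

Double-mutant thermodynamic cycles from pre-steady-state burst kinetics.

`mutcycle` is an R package for biochemists who measure enzyme variants by
single-turnover active-site titration (AST) and want to turn those time
courses into active fractions, activation free energies and coupling
energies between mutated sites. It was built around a 2×2 combinatorial
mutagenesis design on the two Class I aminoacyl-tRNA synthetase signature
motifs (HVGH and KMSKS, mutated to AVGA and AMSAS), but the machinery is
generic for any pair of sites assayed factorially in replicate.

## The model

**Burst kinetics.** An AST time course (signal as a fraction of total ATP)
is fitted to an exponential burst followed by linear steady-state turnover:

    P(t) = A·exp(−k_chem·t) − k_cat·t + C

where `k_chem` is the internal first-order rate constant of the first
catalytic round, `k_cat` the steady-state rate, `A` the burst amplitude and
`C` an offset. Product (ADP, AMP, acyl-tRNA) curves use the same model with
the roles of `A` and `C` inverted and the rate terms' signs flipped, i.e.
`P(t) = n·(1 − exp(−k_chem·t)) + k_cat·t`. The burst counts active enzyme
molecules, so each fit yields two active-fraction estimators — for ATP decay
`n = A·[ATP]/[E]` and `n = (1−C)·[ATP]/[E]` — and nucleotide conservation
demands `n_T = n_D + n_M` (ATP consumed = ADP + AMP produced).

**Thermodynamic cycles.** Rates are converted to activation free energies,
ΔG‡ = −RT ln k (R = 1.987×10⁻³ kcal·mol⁻¹·K⁻¹), because free energies are
additive where rates are multiplicative. Replicate ΔG‡ observations for the
four variant combinations are fitted by ordinary least squares to

    Y = β₀ + β_H·P_H + β_K·P_K + β_HK·P_H·P_K + ε

Under wt01 coding (predictor 1 = native motif present) the interaction
coefficient β_HK equals the classic double-mutant coupling energy
ΔG‡(WT) − ΔG‡(AVGA) − ΔG‡(AMSAS) + ΔG‡(double); negative coupling is
cooperative (favourable). Fits convert exactly between wt01, mut01 and ±1
effect codings, and can be viewed as a cycle: four corner energies and four
signed mutation-step edges that telescope to zero.

A synthetic-data generator produces burst time courses and factorial
free-energy datasets with known ground truth, so every stage is testable by
parameter recovery without any raw assay data.

## Worked example

Fit a noisy simulated ATP-decay curve and estimate the active fraction at
the assay's 5 μM ATP / 3 μM enzyme:

```r
library(mutcycle)
tk  <- true_kinetics("WT", "ATP", n_frac = 0.40, k_chem = 0.02, k_cat = 1e-4)
tc  <- simulate_timecourse(tk, noise_sd = 0.01, seed = 42)
fit <- fit_burst(tc)
fit
#> Burst fit (WT/ATP rep 1, decay): A = 0.3904, k_chem = 0.02007 /s,
#>   k_cat = 0.0001234 /s, C = 0.6124 (R2 = 0.9964)
n_values(fit, assay_conditions(atp_total = 5, enzyme_total = 3))
#>  n_from_A  n_from_C
#> 0.6505892 0.6459802
```

The two estimators agree (0.65 vs 0.65): about two-thirds of the enzyme
molecules are catalytically active, and both recover the generating truth
(0.40 × 5/3 = 0.667) to within the noise. Now a factorial free-energy
dataset with a known anti-cooperative interaction of 0.36 kcal/mol:

```r
truth <- factorial_truth(beta0 = 3, beta_H = 0.45, beta_K = -0.32,
                         beta_HK = 0.36, noise_sd = 0.1, n_replicates = 3)
cyc <- fit_cycle(simulate_factorial_rates(truth, seed = 42))
cyc
#> Thermodynamic-cycle regression (wt01 coding, 12 obs, R2 = 0.9461)
#>   term    estimate     se     t        p
#> 1 beta0      3.04  0.0554 54.8  1.36e-11
#> 2 beta_H     0.442 0.0784  5.64 4.89e- 4
#> 3 beta_K    -0.244 0.0784 -3.12 1.43e- 2
#> 4 beta_HK    0.371 0.111   3.35 1.01e- 2
cycle_view(cyc)$coupling
#> [1] 0.3711
```

All four coefficients are recovered within their standard errors, and the
coupling energy from corner arithmetic equals the fitted interaction. The
positive sign means the two native motifs destabilize the transition state
jointly — they work against one another in this (simulated) catalyst.

`run_pipeline()` chains the stages end to end — simulate or read a variant
panel, fit every curve, aggregate n-values, transform to ΔG‡, fit the
cycle, and check n-value additivity — writing CSV stage tables plus a JSON
summary.

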