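# mutlab

Quantitative toolkit for spontaneous-mutagenesis studies in budding yeast
and for in vitro characterisation of replicative DNA polymerases. It is
aimed at labs running fluctuation assays, sequencing mutant collections,
and measuring polymerase fidelity and processivity on gels — and at anyone
reanalysing the summary tables such studies publish.

Four analysis stages, plus a generator of synthetic inputs with the
statistical structure each stage assumes:

1. **Fluctuation assays.** Parallel cultures grown from small inocula are
   plated on selective medium; mutant counts follow the heavy-tailed
   Luria–Delbrück distribution. `estimate_rate()` estimates the per-cell
   rate μ = m/Nt from the counts by the Lea–Coulson method of the median
   (solving r̃/m − ln m = 1.24), by Ma–Sandri–Sarkar maximum likelihood
   over the exact pmf recursion p₀ = e⁻ᵐ,
   pᵣ = (m/r) Σᵢ pᵢ/(r−i+1) (`ld_pmf()`, `mle_m()`), or by the P0 method
   m = −ln P̂₀ — with distribution-free 95% confidence limits.
   `relative_rate()` and `ci_overlap()` reproduce the reporting
   conventions of published rate tables (rounded relative rates;
   "different" = disjoint confidence limits).
2. **Mutation spectra.** `mc_homogeneity()` tests whether two spectra are
   draws from one multinomial: Pearson χ² on the 2×N table, with the null
   distribution obtained by Monte Carlo re-partition of the pooled
   mutations conditional on both margins (multivariate hypergeometric —
   the construction behind the classical COLLAPSE program), and the
   add-one p-value (1 + k)/(1 + B). `drop_categories()`,
   `percentages()`, `spectrum_correlation()` support the standard
   sensitivity analyses and table summaries.
3. **Polymerase fidelity.** For M13mp2 lacZ forward-mutation assays,
   `error_rate()` computes the per-class, per-detectable-site error rate
   ER = [(Nᵢ/N)×MF]/(D×0.6).
4. **Processivity.** `termination_profile()` converts single-hit gel-lane
   band intensities into per-position termination probabilities —
   T(N) = I_N / Σ_{n≥N} I_n for synthesis, Σ_{n≤N} for 3′→5′ excision —
   and `fold_change()`/`mean_fold_change()` compare enzymes
   position-by-position.

Everything is plain base R with S3 classes (`culture_set`,
`rate_estimate`, `mutation_spectrum`, `lacz_assay`, `lane_profile`,
`termination_profile`) and print/plot/confint methods. TSV readers and
writers (`read_cultures()`, `read_spectra()`, `read_lanes()`,
`read_lacz()`, `rate_table()`, …) round-trip every dialect, and a thin
command-line wrapper ships at
`system.file("scripts", "mutlab.R", package = "mutlab")` with subcommands
`rates`, `spectra`, `fidelity`, `processivity`, `simulate`.

## Worked example

Estimate rates from a simulated 45-culture fluctuation assay and compare a
mutator to wild type:

```r
library(mutlab)
wt  <- simulate_cultures(mu = 1e-8, nt = 1e8, n_cultures = 45, seed = 43,
                         strain = "wt", locus = "CAN1")
mut <- simulate_cultures(mu = 1e-7, nt = 1e8, n_cultures = 45, seed = 42,
                         strain = "mutator", locus = "CAN1")
estimate_rate(mut)
#> Mutation-rate estimate (mutator / CAN1)
#>   method: median   cultures: 45
#>   m (events/culture): 12.7
#>   rate: 1.27e-07 per cell per generation  (95% CI 1.03e-07 - 1.43e-07)
relative_rate(estimate_rate(mut), estimate_rate(wt))
#> [1] 14.3
!ci_overlap(estimate_rate(mut), estimate_rate(wt))   # "different"?
#> [1] TRUE
```

The estimated rate (1.27×10⁻⁷) recovers the simulated truth (10⁻⁷) within
the sampling error of 45 cultures; the mutator is called significantly
different from wild type because the 95% limits are disjoint.

Compare the published mutant-class distributions of two
exonuclease-deficient polymerase forms (counts over substitutions, −1
frameshifts, +1 frameshifts, other):

```r
classes <- c("substitutions", "-1 frameshifts", "+1 frameshifts", "other")
holo   <- mutation_spectrum(c(214, 53, 9, 11), classes, label = "holoenzyme pol2-4")
twosub <- mutation_spectrum(c(229, 35, 7, 29), classes, label = "pol2-4/Dpb2")
mc_homogeneity(holo, twosub, B = 1e5, seed = 17)
#>  Monte Carlo Pearson chi-squared test of spectrum homogeneity
#> data:  holoenzyme pol2-4 vs pol2-4/Dpb2
#> X-squared = 12.258, B = 100000, p-value = 0.00644
mc_homogeneity(drop_categories(holo, "other"),
               drop_categories(twosub, "other"), B = 1e5, seed = 17)
#> X-squared = 4.3944, B = 100000, p-value = 0.1082
```

The two spectra differ (p ≈ 0.006), but not after removing the
heterogeneous "other" class (p ≈ 0.11): the difference is carried entirely
by that class — the published conclusion this reproduces.

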