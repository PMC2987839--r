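---
title: "Methods: fluctuation analysis, spectrum homogeneity, fidelity, and processivity"
author: "mutlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluctuation analysis, spectrum homogeneity, fidelity, and processivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutlab)
```

mutlab implements the four quantitative stages of a classical
spontaneous-mutagenesis study in *Saccharomyces cerevisiae*, together with a
synthetic-data generator that emulates the statistical structure each stage
assumes. This vignette is the package's account of the underlying models,
the tunable parameters and their defaults, the numerical choices, and the
limits of what the tests demonstrate.

## 1. Fluctuation assays and the Luria–Delbrück distribution

In a fluctuation assay, many parallel cultures are grown from small inocula
(so that pre-existing mutants are essentially absent), and each culture is
plated on selective medium. A mutation arising early in the growth of a
culture founds a large mutant clone ("jackpot"); a late mutation founds a
small one. The per-culture mutant counts therefore follow the heavy-tailed
Luria–Delbrück distribution, parameterised by $m$, the expected number of
mutation *events* per culture. The per-cell, per-generation rate is
$\mu = m / N_t$, where $N_t$ is the number of cells per culture at plating
(for exponential growth from a small inoculum, the number of cell divisions
is $\approx N_t$). $N_t$ is always a user input — it differs between
strains and media and is never hard-coded. A `plating_fraction` in $(0,1]$
rescales the effective $N_t$ when only part of a culture is plated; the
default is 1, matching protocols with no dilution correction.

### Estimators

* **Method of the median** (`estimate_rate(..., method = "median")`, the
  default): the Lea–Coulson equation
  $\tilde r / m - \ln m = 1.24$
  is solved for $m$, where $\tilde r$ is the sample median count (the mean
  of the two central order statistics for even $n$). The left-hand side is
  strictly decreasing in $m$, so the root is unique; `uniroot()` locates it
  to a relative tolerance of $10^{-10}$. This is the standard estimator
  behind "rates were obtained as the median of $n$ independent cultures"
  protocols: it is robust to jackpots, which dominate the mean but barely
  move the median.
* **MSS maximum likelihood** (`method = "mle"`): the exact
  Ma–Sandri–Sarkar recursion
  $p_0 = e^{-m}$, $p_r = \frac{m}{r}\sum_{i=0}^{r-1}\frac{p_i}{r-i+1}$
  gives the Luria–Delbrück pmf (`ld_pmf()`), and the likelihood is
  maximised by bounded one-dimensional search. The recursion costs
  $O(r_{\max}^2)$, so counts above a cap (default 1000) are treated as
  right-censored through the tail probability $1 - \sum_{r \le cap} p_r$ —
  jackpot cultures then still contribute their full information content
  ("a very large count occurred") at bounded cost. The MLE serves mainly
  as an independent cross-check of the median method; the two agree within
  sampling error on simulated assays.
* **P0 method** (`method = "p0"`): $m = -\ln \hat P_0$ with $\hat P_0$ the
  fraction of zero-mutant cultures. Because a culture has zero mutants
  exactly when it had zero mutation events, $P_0 = e^{-m}$ holds exactly
  under the model. `estimate_rate()` falls back to this method
  automatically (with a message) when the median is zero, where the
  Lea–Coulson equation is uninformative.

### Confidence intervals

The cited experimental protocols do not specify a CI procedure, so the
package makes a documented, reproducible choice: the distribution-free
binomial order-statistic interval on the median count (the largest $j$ with
$P(\mathrm{Bin}(n, \tfrac12) < j) \le \alpha/2$ gives bounds
$r_{(j)}, r_{(n-j+1)}$), with each bound mapped through the Lea–Coulson
transform and divided by $N_t$. Because the transform is monotone, the
interval always brackets the point estimate. Rank intervals on a discrete
heavy-tailed distribution are conservative and approximate; the test suite
asserts empirical coverage of at least 85% at a nominal 95% rather than
exactness. The P0 method uses the exact binomial interval on $\hat P_0$
mapped through $-\ln$; the MLE uses the profile-likelihood interval.

### Reporting conventions

`relative_rate()` divides a strain's rate by a reference (wild-type) rate
and rounds the way published rate tables print: one decimal place below
100 and three significant figures at or above 100, with halves rounded
away from zero. This convention was chosen because it reproduces the
printed relative-rate columns (including suppression ratios below 1,
e.g. $26/74.3 \to 0.3$); a fixed significant-figure rule does not.
`ci_overlap()` implements the tables' significance call — two rates are
"different" when their 95% intervals are disjoint; a shared endpoint
counts as overlap (the conservative reading).

## 2. Mutation-spectrum homogeneity

A mutation spectrum is a vector of mutant counts by class (six base
substitution types, ±1 frameshifts, complex, other — or the coarser
in vitro classes). Two spectra over the same classes form a $2 \times N$
contingency table; the question "could both have arisen from one
underlying multinomial?" is answered by a Monte Carlo version of the
Pearson $\chi^2$ test, because expected counts in sequenced spectra are
routinely far below the asymptotic regime.

`mc_homogeneity()` computes the observed Pearson statistic, then draws $B$
(default $10^5$) null tables *conditional on both margins*: the pooled
mutations are randomly re-partitioned into two groups of the observed
sizes, i.e. the group-1 row is a multivariate hypergeometric draw. This is
the label-permutation construction used by the classical COLLAPSE program
for spectrum comparison. The implementation draws each category's
allocation with vectorised `rhyper()` across all $B$ resamples, so the
test costs $O(BN)$ time.

Numerical choices:

* The p-value is the add-one estimator $p = (1 + k)/(1 + B)$, where $k$
  resampled statistics reach the observed one; it is never exactly zero,
  and equals 1 for identical spectra (every resample has
  $\chi^{2*} \ge 0$).
* Resampled statistics are compared with the observed value using a
  $10^{-9}$ slack so that exact ties count toward the tail; without it,
  floating-point noise could push a tied statistic to the wrong side.
* Categories with zero pooled count are dropped before the test (their
  expected counts are zero and the statistic is undefined); at least two
  usable categories must remain.
* Columns may have unequal totals (a sequenced isolate can carry two
  mutations); no normalisation is applied.
* The seed is a required argument: a resampling p-value without a recorded
  seed is not reproducible.

`drop_categories()` supports the standard sensitivity analysis of removing
a heterogeneous class (e.g. "other mutations", which pools long deletions
with complex events) and re-testing. `percentages()` reproduces printed
per-class percentages (half-up rounding, one decimal by default), and
`spectrum_correlation()` gives the Pearson correlation of the two
proportion vectors as a descriptive supplement (requiring $\ge 3$
categories; with two, the correlation is always $\pm 1$).

The type-I error of the test at the 0.05 level is checked by simulation
(1000 null pairs of 48-mutant spectra drawn from one realistic 10-class
multinomial) and required to fall in $[0.03, 0.07]$; on small $2\times 2$
tables the Monte Carlo p-value is checked against exact hypergeometric
enumeration to within 0.005 at $B = 10^6$.

## 3. lacZ forward-mutation fidelity

The M13mp2 lacZ gap-filling assay measures polymerase fidelity in vitro:
a single-stranded lacZ region is copied by the polymerase of interest, the
products are introduced into *E. coli*, and mutant (light blue or
colourless) plaques are scored. `mutant_frequency()` is the plain plaque
fraction. Sequencing $N$ independent mutants classifies the errors, and
the per-class error rate is

$$ER_i = \frac{(N_i / N) \times MF}{D_i \times 0.6},$$

with $N_i$ the number of class-$i$ mutations among the $N$ sequenced
mutants, $MF$ the lacZ mutant frequency, $D_i$ the number of template
sites at which a class-$i$ mutation is phenotypically detectable, and 0.6
the probability that a mutant lacZ allele is expressed in *E. coli*. The
expression probability defaults to 0.6 but is configurable
(`expression_prob`). The detectable-site counts $D_i$ come from the assay
literature and are always user inputs. Because one mutant can carry
several mutations, $\sum_i N_i$ may exceed $N$; the package deliberately
does not reconcile them. `background_adjusted_frequency()` subtracts the
background frequency of uncopied DNA, truncating at zero and flagging
frequencies at or below background as unresolvable.

## 4. Processivity as per-position termination probabilities

Under single-hit conditions (at most one enzyme encounter per
primer-template), the band intensity $I_N$ at product length $N$ on a
denaturing gel counts the molecules whose synthesis (or excision)
terminated at $N$. The chance that an enzyme that reached position $N$
dissociates there is then

* synthesis: $T(N) = I_N / \sum_{n \ge N} I_n$,
* excision: $T(N) = I_N / \sum_{n \le N} I_n$,

the denominator being "molecules that got at least this far" in the
direction of travel. Positions are product lengths in nucleotides,
1-based; unquantified gel positions are absent, not zero. When a
`runoff_position` is set (the full-length or fully-degraded band), that
band stays in the denominators — those molecules did pass every position —
but is excluded from the reported profile, because running off the
template is completion, not termination. Whether published profile figures
include the runoff band in denominators is generally not stated; this
convention is the package's documented choice and is configurable by
simply not flagging the band. Positions with zero denominator are omitted
with a message.

`fold_change()` compares two enzymes position-by-position (e.g. a
two-subunit complex against the four-subunit holoenzyme), using only
positions quantified in both profiles with a positive reference value.
`mean_fold_change()` summarises the ratio map by its geometric mean —
the natural average for multiplicative quantities — and attaches the
arithmetic mean as an attribute for transparency.

A conservation identity pins the computation down: reconstructing
$P(\text{stop at } N) = T(N)\prod_{\text{earlier } n}(1 - T(n))$ must
return exactly the lane's raw intensity fractions in the noise-free case,
and reversing positions maps the excision formula onto the synthesis one.
Both are asserted in the tests.

## 5. The synthetic-data generator

Real per-culture counts, per-plaque data, and phosphoimager tables from
the motivating experiments are not deposited anywhere; the published
summaries are the only real inputs. The generator therefore produces
inputs with the *assumed statistical structure* of each stage, so every
analysis path is testable end-to-end:

* `simulate_cultures()`: mutation events per culture are
  $\mathrm{Poisson}(m)$ with $m = \mu (N_t - N_0)$; each event founds a
  clone of size $\lfloor 1/u \rfloor$, $u \sim U(0,1)$ — the
  deterministic-exponential-growth clone-size law whose $1/x^2$ tail
  produces jackpots — capped at $N_t$, as is the per-culture total. Rates
  above 0.1 per cell are rejected as absurd. Defaults in the tests are
  $\mu = 10^{-7}$, $N_t = 10^8$ (so $m = 10$, a typical forward-mutation
  assay operating point) with 9–45 cultures, the culture numbers the
  protocols use.
* `simulate_spectrum()`: a single multinomial draw of $n$ mutations over
  the class probabilities (48 mutants per strain is the realistic
  sequencing depth used in the calibration tests).
* `simulate_lane()`: molecules are apportioned *deterministically* down
  the template — the count stopping at position $N$ is
  $n \cdot T(N) \prod_{\text{earlier}}(1-T)$, survivors accumulate in the
  runoff band — and measurement noise is multiplicative Gaussian per band
  ($I = c(1 + \varepsilon)$, $\varepsilon \sim N(0, cv^2)$, floored at 0),
  emulating phosphoimager quantification error, which is roughly
  proportional to signal. The deterministic ensemble average makes the
  zero-noise round trip exact, which is what the conservation tests
  exploit; it deliberately omits molecule-level binomial noise.
* `simulate_lacz()`: class counts $N_i$ are multinomial with
  probabilities $ER_i D_i \cdot 0.6 / MF$ (which must sum to at most 1;
  any remainder becomes unclassified mutants outside the reported
  classes), so `error_rate()` on the output recovers the inputs within
  sampling error.

All generators take an explicit seed, are bit-reproducible given it, and
restore the caller's RNG state.

**What passing tests do and do not show.** The generator realises the
idealised models: no phenotypic lag, full plating efficiency, no
differential mutant fitness, perfect single-hit gels, no gel-position
misassignment. Agreement on synthetic data therefore validates the
*computations*, not the biological adequacy of the models for any given
real assay; deviations from these assumptions in real data (e.g. partial
plating without the `plating_fraction` correction, or multi-hit gel
conditions) bias the corresponding estimates in known directions and are
the user's responsibility to control experimentally.

## 6. Problem sizes and runtime choices

The simulation-based checks use sizes a desk reanalysis would pick:
$B = 10^5$ resamples for headline p-values (Monte Carlo SE
$\approx 2\times10^{-4}$ at $p = 0.005$), $B = 999$ inside calibration
loops of 200–1000 replicates, 45-culture assays with 100–500 replicates
for recovery and coverage, and an MLE censoring cap of 1000. These keep
the full suite in tens of seconds on one CPU while leaving every
tolerance comfortably wider than the Monte Carlo noise at these sizes.

## 7. Known limitations

* The Lea–Coulson median equation is itself an approximation; its small
  bias at large $m$ is inherited by the rate estimates (the recovery test
  allows 20%).
* Rank-based CIs on discrete medians are conservative and can be wide for
  small culture numbers.
* The homogeneity test conditions on both margins; it tests association,
  not any parametric alternative, and has limited power at 48 mutants per
  spectrum.
* Per-site (positional) spectrum comparison along a gene, hotspot
  detection, and simultaneous comparison of more than two spectra are out
  of scope.
* Gel image densitometry is upstream of the package: the processivity
  module starts from band-intensity tables.
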