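---
title: "Dual-isotope tracer accounting: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-isotope tracer accounting: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycotrace)
```

## The scientific problem

When a tree is pulse-labelled aboveground with ^13^CO~2~ and ^15^NH~4~^+^,
the two tracers move down the stem, through the root system and into the
fungal partners of the ectomycorrhizal (EM) symbiosis. `mycotrace`
implements the accounting needed to turn raw isotope-ratio measurements of
harvested tissues into statements about *allocation*: how much newly
acquired carbon and nitrogen each compartment received, how that allocation
is partitioned among co-occurring fungal taxa, and whether the carbon and
nitrogen each taxon receives is predicted by the stoichiometry (C/N ratio)
of the symbiotic organ itself.

The package covers five layers:

1. **Isotope bookkeeping** — δ notation to atom fraction, atom-percent
   excess (APE) against non-labelled controls, enrichment concentrations,
   and compartment amounts.
2. **Community census** — colonization and vitality rates from root-tip
   counts, morphotype relative abundances, Bray–Curtis/ANOSIM comparison of
   assemblages between sampling dates.
3. **Pool partitioning** — taxon-specific EM pools (enrichment × tip
   biomass × tip number), root and rhizosphere pools, shares and C:N
   transfer ratios.
4. **Stoichiometric statistics** — OLS regressions of enrichment on C/N
   and on lateral-root enrichment, slope tests against 1, comparison of
   regression lines, the C/N threshold (regression x-intercept) with a
   bootstrap interval, Tukey–Kramer letters, Welch control tests, two-way
   block ANOVA.
5. **Synthetic studies** — a fully seeded generator producing every input
   table with complete ground truth, so each estimator can be scored by
   parameter recovery.

## Isotope model

For an isotope system with standard ratio $R_{std}$ (VPDB
$^{13}C/^{12}C = 0.0111802$; atmospheric N~2~ $^{15}N/^{14}N = 0.0036765$),
a measurement of δ (‰) maps to the heavy-atom fraction

$$x = \frac{R}{1+R}, \qquad R = R_{std}\left(\frac{\delta}{1000}+1\right).$$

The tracer signal is the atom-percent excess
$\mathrm{APE} = (x_{labelled} - \bar{x}_{control}) \times 100$, with the
control mean taken over the non-labelled plants *per compartment and
isotope system*. A compartment-wise control mean is the least-assumption
choice when controls are unpaired; it also absorbs compartment-specific
natural-abundance differences (e.g. soil vs plant tissue).

The enrichment concentration (mass of newly acquired heavy isotope per gram
dry tissue) is

$$E = \frac{\mathrm{APE}}{100}\times 1000 \times
\frac{m_{element}}{m_{dry}} \quad [\mathrm{mg\,g^{-1}}],$$

reported in mg g^−1^ for ^13^C and µg g^−1^ for ^15^N — the two tracers
arrive at very different absolute levels, and a shared unit would bury the
^15^N signal in leading zeros. Amounts are enrichment × compartment dry
biomass, summed over compartments where a pool spans several (fine +
coarse roots). Negative APE values — possible whenever a labelled sample
sits below the control mean through measurement noise — are **retained and
flagged**, never clipped: clipping would bias compartment means upward,
and the downstream linear models are exactly the place where symmetric
noise should be allowed to cancel.

## Community statistics

Census indices follow the standard root-tip bookkeeping: colonization is
vital mycorrhizal over all vital tips (dry tips excluded), vitality is
vital over all counted tips. Relative abundance divides each morphotype's
tip count by the plant's vital mycorrhizal tips; tips not assigned to any
named species remain in an explicit `unclassified` column. That column is
carried for bookkeeping but *excluded* from the ANOSIM comparison —
silently renormalizing the named species would distort Bray–Curtis
distances between plants with different classification completeness.

ANOSIM ranks all pairwise Bray–Curtis dissimilarities jointly (midranks on
ties, standard practice) and uses

$$R = \frac{\bar{r}_{between} - \bar{r}_{within}}{n(n-1)/4},$$

which is bounded in $[-1, 1]$ and equals 1 when every between-group pair
is more dissimilar than every within-group pair. The p-value is
$(1 + \#\{R_{perm} \ge R_{obs}\})/(B+1)$ over seeded label permutations
(default $B = 9999$; the seed is a mandatory argument and is recorded in
the result). `anosim_exact()` enumerates all label assignments for small
studies and is used in the tests to verify the sampled p-value. Whether
abundances or raw counts enter the comparison is a switch
(`use_relative`, default relative abundances).

## Pool partitioning

The EM pool of a plant is
$\sum_i E_i \, b_i \, (a_i \, T)$ over fungal species $i$, with enrichment
$E_i$, per-tip dry biomass $b_i$, relative abundance $a_i$ and total EM tip
count $T$. Tip numbers $a_i T$ are kept real-valued internally and rounded
only for display: $T$ is of order 3 × 10^4^, and rounding per-species
products would systematically bias rare taxa. Shares are reported
unrounded (e.g. an EM share of fine-root ^13^C of 5.87%) so the reader can
see both the precise value and its rounded counterpart. The coarse:fine
contrast is computed as $(\text{total root} - \text{fine root})/\text{fine
root}$ and labelled as such. C:N transfer ratios convert mg ^13^C to µg
before dividing by µg ^15^N. Published per-plant mean pools give a root
ratio near 1100; a previously reported root-level value of 259 cannot be
reconstructed from any reported pool pair, so the package documents its own
unit-harmonized definition rather than matching that number.

## Regression layer

All fits are ordinary least squares; `fit_linear()` keeps slope/intercept,
their standard errors, Pearson's *r* and the slope's t-test on $n-2$ df.
Three derived tests matter for the allocation questions:

* **Slope against 1** (`test_slope_against_value`): is the symbiont
  enriched beyond proportionality with its supporting lateral rootlet?
  $t = (\hat\beta - 1)/SE(\hat\beta)$, one- or two-sided.
* **Comparison of regression lines** (`compare_regression_lines`): the
  pooled-variance slope contrast on $n_1+n_2-4$ df, algebraically equal to
  the interaction t-test in the dummy-variable regression `y ~ x * group`
  (the tests verify this identity to 10^−9^).
* **C/N threshold** (`x_intercept_threshold`): the fitted line crosses zero
  at $-\hat\alpha/\hat\beta$; above this C/N the model predicts essentially
  no further allocation. The estimate is only issued when the slope itself
  is significant (a flat line has no meaningful root), and uncertainty
  comes from a percentile bootstrap over case resamples (default
  $B = 2000$, seeded). Fieller-type intervals were considered; the
  case-resampling bootstrap was chosen because it is assumption-light and
  behaves sensibly when the x-intercept sits near the edge of the observed
  C/N range. Degenerate resamples (constant x) are dropped from the
  bootstrap distribution.

For reference coefficients like the ^13^C fit the threshold arithmetic
gives $57.1/2.49 = 22.93$ C/N units; the package reports this x-intercept
and its CI rather than forcing agreement with coarser rounded field statements
("about 24") whose derivation is not reproducible.

Group comparisons use one-way ANOVA with Tukey–Kramer pairwise p-values
(studentized range with unequal-n standard errors) and a compact letter
display built by insert-and-absorb with groups pre-sorted by descending
mean, which makes the letters deterministic and guarantees the defining
property: two groups share a letter exactly when their adjusted p exceeds
α. Residual normality is screened with Shapiro–Wilk (p < 0.05 triggers a
log transform when `log_transform = "auto"`); a visual-inspection rule is
not reproducible, an automated gate is, and it can be switched off. With
two sampling dates a random date effect is not estimable, so compartment
effects are tested by a fixed-block two-way ANOVA (`response ~ tissue +
time`, no interaction by default), matching the usual practice of pooling
dates when the time term is non-significant. Tests of labelled tissue
against non-labelled controls are one-sided Welch t-tests — under pulse
labeling, enrichment can only sit at or above natural abundance.

## The synthetic generator and what it does (not) show

`simulate_study()` inverts the analysis. Communities come from a Dirichlet
with mass concentrated on 7 dominant of 16 species so the dominants cover
~80% of tips in expectation; tip counts are multinomial within a census of
~400 inspected tips per plant, with colonization ~92.6% and vitality
~89.6%; total EM tips per plant are drawn around 29,215 (SD 4,361).
Species-level C/N is uniform on 7–30 with small per-plant jitter (C/N
clusters by species in real data); carbon concentration is uniform on
380–440 mg g^−1^ and nitrogen is *derived* as C/(C/N) — the three printed
ranges are not jointly satisfiable, and C/N is the predictor that drives
the models, so it takes priority. True enrichments follow the linear
models (^13^C: 57.1 − 2.49·C/N, noise SD 5 mg g^−1^; ^15^N: 15.1 −
0.57·C/N, noise SD 2 µg g^−1^); lateral-root enrichment is the EM value
divided by the coupling slope (1.23 / 0.53) plus noise; bulk compartments
(bark, coarse/fine roots, rhizosphere soil) get means back-solved from the
published per-plant pool sizes at the default biomasses (fine root 3.9 g,
coarse 12.5 g, rhizosphere soil 54 g). Everything is then pushed backwards
through APE into δ values (controls at −28‰ ^13^C / 0‰ ^15^N, SD 0.5‰),
so the measurement tables look like what an isotope-ratio mass
spectrometer would deliver.

Two deliberate modelling points:

* **Rectification.** Real tissues cannot be *depleted* below natural
  abundance by labeling, so generated enrichments are rectified at zero by
  default (`truncate_enrichment = TRUE`), mimicking the convergence to
  zero at high C/N. Rectification makes naive refits of the generating
  slope biased toward zero — ground truth keeps the unrectified draws so
  this bias can be quantified. Parameter-recovery checks therefore use the
  untruncated mode (`truncate_enrichment = FALSE`) or generate the
  regression data directly, which is also the only regime in which the
  Gaussian linear model is fully realizable: at high C/N the ^13^C model
  predicts enrichments below the physical floor of δ-space bookkeeping
  (APE cannot fall below −100 × the natural-abundance atom fraction), so
  a measurement-level simulation necessarily departs from the idealized
  line there. This is a genuine limitation of a linear enrichment model
  across the full C/N range, not of the estimators.
* **No time effect.** Both sampling dates share one community and one
  enrichment model; the generator intentionally contains no temporal
  kinetics, so a correct ANOSIM should be non-significant between dates.

Passing recovery tests on these studies shows the estimators are unbiased
and correctly sized *under the generating model* — independent Gaussian
noise, exact species identification, no IRMS drift, no spatial structure
among plants. Real data can violate any of these; the tests say nothing
about such violations.

## Problem sizes and numerical choices

The test-suite simulations are sized to keep full runs near 20 seconds:
recovery means use 200 replicates of 33–40-point fits, bootstrap coverage
uses 300 replicates at $B = 600$, the ANOSIM null check uses 10^4^
permutations, and end-to-end pipeline tests use 8–10-plant studies. Seeds
are fixed in every stochastic test and mandatory in every stochastic API
(`anosim`, `x_intercept_threshold`, the generator, `run_full_analysis`).
Tolerances: algebraic identities at 10^−9^–10^−12^, parameter recovery at
the width implied by the replicate SE (±0.1 for the C/N slope, ±0.05 for
the coupling slopes), Monte-Carlo comparisons at $2/\sqrt{B}$.

Degenerate inputs are errors, not silent numbers: constant x in a
regression, a flat slope feeding a threshold, a census with no vital tips,
two all-zero abundance profiles in Bray–Curtis, groups of size 1 in ANOSIM
or ANOVA, missing controls for a compartment×isotope, and mixed δ/atom
fraction dialects in one measurement table all raise classed conditions
(`mycotrace_error_*`) that name the offence.

## A short worked example

```{r example, eval = FALSE}
study <- simulate_study(simulation_config(), seed = 42)
report <- run_full_analysis(study, seed = 7)
report
report$thresholds
write_report(report, "analysis_out")
```

## Known limitations

* The linear enrichment~C/N model cannot hold across the whole observed
  C/N range in measurement space (see the rectification discussion above);
  a saturating or hinge model would be a natural extension.
* "Time as random factor" is approximated by a fixed block; with only two
  dates nothing more is estimable.
* Morphotype identities are input labels; mis-identification and the
  image-analysis steps that produce cross-section areas are upstream of
  this package.
* Extramatrical mycelium is not separated from the bulk rhizosphere pool.
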