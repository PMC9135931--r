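---
title: "Membrane fatty-acid indexes and brain aging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane fatty-acid indexes and brain aging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidaging)
```

## The data and its constraints

A gas-chromatography fatty-acid profile of total brain lipids is a
*composition*: 25 acyl species expressed in mol%, summing to 100 by
construction (closure). Closure has two consequences that shape every
design decision in this package. First, the parts are not independent —
an increase in one species mechanically depresses the others. Second,
values are nonnegative, and the small species (0.02–0.5 mol%) sit close
to the boundary, so additive Gaussian error models are wrong for them.

The data model is deliberately plain: a *profile* is a named numeric
vector over the 25-species panel (`fa_panel()`), and a *cohort* is a
wide tibble with one row per subject × region, metadata columns
(`subject_id`, `region`, `age`, `sex`, `pmt_hours`) and one column per
species. Both naming dialects seen in practice (`22:6n-3`, `22:6n3`)
are parsed; output is always hyphenated. A species absent from a
profile is *missing*, not zero: index computation refuses partial
profiles, because silently zero-filling a missing species biases every
weighted index downward. Callers who know a species was measured as
absent must impute 0 explicitly.

Profile validation (`validate_profile()`) accepts a closure deviation
up to 1.0 mol% by default: published group-mean tables, rounded to two
decimals per cell, close only to within a few hundredths, and 25 cells
× 0.005 rounding each bounds the plausible deviation well under 1.
`renormalize()` restores exact closure by scaling, which preserves all
between-species ratios.

## The indexes

All indexes are computed from double-bond counts and chain lengths
derived by the parser, never from hard-coded species lists, so they
remain valid for extended panels:

- `ACL = Σ_C (total mol% with C carbons) × C / 100` — mean carbons per
  chain, grouping by carbon count only.
- Class totals: SFA (0 double bonds), MUFA (1), PUFA (≥ 2, split into
  n-3 and n-6 series), UFA = MUFA + PUFA, and the SFA/UFA ratio
  (undefined, not an error, when UFA = 0).
- `DBI = Σ_k k · (mol% with k double bonds)` — double bonds per 100
  chains.
- `PI = 0.025·mono + 1·di + 2·tri + 4·tetra + 6·penta + 8·hexa` — the
  classical peroxidizability weighting, near-zero for monoenes and
  steeply increasing with the number of bis-allylic positions.

ACL, the class totals, DBI and PI are linear in the composition, so the
mean of per-subject indexes equals the index of the mean profile. This
licenses checking recomputed indexes against published group-mean
compositions, and it is asserted as a property test. The SFA/UFA ratio
is *not* linear: the package computes it per subject and averages the
ratios, and documents that the ratio of group means differs. The same
applies to the activity ratios below — conspicuously for PβOx, where
the packaged reference table's group values are visibly means of
per-subject ratios rather than ratios of means.

## Surrogate activities

Desaturase, elongase and peroxisomal β-oxidation activities are
estimated as product/substrate mol% ratios (17 definitions in
`builtin_ratio_table()`). These are surrogate indices, not rates: they
assume the precursor pool is at quasi-steady state. Ratios cancel the
closure constant, so activities are invariant under renormalization — a
tested property. A ratio is reported as undefined (`NA`) when its
denominator falls below 1e-6 mol%, rather than propagating infinities;
measured compositions bottom out around 0.02 mol%, three orders of
magnitude above the threshold, so the guard only ever fires on
synthetic or degenerate input. Two of the printed n-3 elongase
definitions overlap mechanistically (22:5n-3/20:5n-3 and
24:5n-3/22:5n-3 both involve Elovl2); the table reproduces the
conventional assignments verbatim without adjudicating the enzymology.

## Statistics

**Age groups.** Subjects split at 60 years: `age < 60` middle-aged,
`age ≥ 60` elderly. The reference cohort (ages 40–79, `table1_ages()`)
contains no subject aged exactly 60, so the boundary convention is
free; ties go to the elderly group and the choice is documented rather
than load-bearing.

**Group tests.** Student's pooled-variance t-test is the default
(`t_variant = "student_pooled"`); Welch is available and is the default
for `t_from_summary()`, which reconstructs a test from printed
mean ± SEM ± n so users can sanity-check published star coding when raw
data are not deposited. Both variants are cross-checked against
closed-form recomputation to 1e-10 in the tests. Percent change is
signed, elderly relative to the middle-aged baseline, and the reporting
layer renders magnitude + direction to mirror conventional prose.

**Multiple testing.** Benjamini–Hochberg step-up at maximum discovery
rate Q = 0.10, via `stats::p.adjust`; the test suite verifies the
discovery set against an exhaustive scan of all step-up thresholds on
1,000 random p-vectors. The adjustment family is *per region* across
the variables reported together for that region (25 species + 9
indexes + SFA/UFA + PβOx), with the 17 activities adjusted as their own
per-region family — matching how the per-region result tables are
organized; the alternative (one global family) is stricter and can be
obtained by calling `bh_adjust()` on the pooled p-values. Because the
intended family is not stated anywhere authoritative, outputs always
carry both `p_raw` and `q_adj` and never claim to reproduce any
published adjusted column.

**Correlation with age.** Spearman's rho on average ranks. The p-value
uses the t-approximation `t = ρ√((n−2)/(1−ρ²))`; for untied samples
with n ≤ 9 an exact two-sided permutation p over all n! rank orders is
used instead (the enumeration is the package's own; tests compare it
against an independent lexicographic enumeration and against the
classical exact small-sample distribution). Ties fall back to the
approximation. Cross-region matrices (`correlation_matrix()`) pair
subjects by `subject_id` with pairwise-complete deletion and leave any
pair with fewer than 3 shared subjects undefined.

## The simulator

`simulate_cohort()` exists so that every pipeline stage can be
exercised, and its error rates measured, without raw subject data. It
emulates exactly the structure the analysis assumes:

- **Logistic-normal noise.** Per species, log-abundance is drawn as
  `log(m_i) − σ_i²/2 + slope_i·(age − 60) + ε_i`, `ε_i ~ N(0, σ_i²)`
  independent, then the vector is exponentiated and renormalized to
  100. Positivity and exact closure hold by construction — the two
  structural facts of the data. Independent Gaussians on mol% would
  guarantee neither.
- **SEM calibration.** The target per-subject SD of species *i* is
  `SEM_i · √n` from the template (n = 9 middle-aged, 8 elderly by
  default). Renormalization absorbs part of the drawn variance, so the
  required pre-closure CV is obtained by a fixed-point solution of the
  first-order (delta-method) closure variance, and then converted to a
  log-scale SD by exact lognormal moment matching
  (`σ² = log(1 + cv²)`); the `−σ²/2` term makes the pre-closure mean
  exact. The calibration is approximate under closure; the tests assert
  recovery of template means within 3 Monte-Carlo standard errors and
  of target SDs within ±20% for species ≥ 0.1 mol% at n = 10,000. In
  practice the calibration lands within a few percent.
- **Printed-zero SEMs.** Reference SEMs are printed to two decimals, so
  "0.00" means "< 0.005"; template construction floors SEMs at 0.005
  mol% (half the last printed digit) to keep noise strictly positive.
- **Age effects.** Injected *before* closure, so a positive trend on
  one species induces small compensatory negative trends elsewhere —
  the compositional coupling real aging trends must exhibit. Default
  ages are uniform on 40–80 years (the reference cohort's range),
  rounded to whole years; `table1_ages()` reproduces the exact 9/8
  group structure.
- **Determinism.** The seed in `sim_config()` fixes ages and all noise;
  identical configurations yield bit-identical cohorts on the same
  platform and library versions.

What the simulator does **not** emulate: between-species correlation
beyond what closure induces (only marginal SEMs are published, so the
log-scale covariance is diagonal — an explicit simplification), sex or
post-mortem-time structure, and any nonlinearity in age (e.g. a
mid-life breakpoint). Passing calibration tests therefore demonstrate
correctness of the pipeline under this generative model, not fidelity
to every feature of real cohorts.

## Problem sizes and numerical choices in the test suite

The calibration checks run at sizes chosen to balance statistical
resolution against runtime: 200 seeded null replicates of the
17-subject design for uniformity and FDR control (the p-value
uniformity check asserts a Kolmogorov–Smirnov *distance* bound of 0.05
rather than an asymptotic KS p-value, which would be meaningless at
pooled n ≈ 7,000 under mild lognormality; the type-I band 0.05 ± 0.015
allows for the negative correlation closure induces among variables of
one replicate); 100 replicates at n = 100 for slope-sign recovery; and
a single n = 10,000 draw for moment recovery. The power check targets
20:0 at its panel-typical measurement precision: statistical power at
the fixed slope of 0.01/yr depends strongly on the assumed noise, and
for the occasional species whose published SEM implies a CV near 1 the
same slope is simply not detectable at n = 100 — a property of the
design, not of the implementation.

## Known limitations

- Published per-subject raw data are not deposited, so published t, ρ
  and p values cannot be reproduced; the reference table supports
  index self-consistency, percent-change and ordering checks only.
- Activity and ratio comparisons against group-mean profiles use the
  ratio-of-means as a surrogate for the mean-of-ratios; the two agree
  only approximately, and the tests that rely on the surrogate say so.
- The odd-chain, branched and trans species occasionally reported in
  brain lipidomics are outside the parser's grammar by design.
- The cohort reader requires the closed 13-region vocabulary; mapping
  other anatomical naming schemes onto it is the caller's
  responsibility (`brain_regions(anatomy = TRUE)` documents the
  intended anatomy).
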