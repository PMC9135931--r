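# lipidaging

Fatty-acid compositional analysis of human brain aging.

Gas-chromatography profiling of total-lipid fatty acids yields, for each
tissue sample, a composition: the mol% of each acyl species among all
quantified species, summing to 100 by construction. `lipidaging`
implements the standard analysis of such profiles across brain regions
and age:

- **Membrane indexes.** Average chain length
  `ACL = Σ_C (mol% with C carbons) · C / 100`; class totals (SFA, UFA,
  MUFA, PUFA, PUFAn-3, PUFAn-6, SFA/UFA); double bond index
  `DBI = Σ_k k · (mol% with k double bonds)`; peroxidizability index
  `PI = 0.025·monoenoic + 1·dienoic + 2·trienoic + 4·tetraenoic +
  6·pentaenoic + 8·hexaenoic`, a weighted susceptibility of the membrane
  to lipid peroxidation.
- **Surrogate enzyme activities.** Seventeen product/substrate mol%
  ratios estimating desaturase (D9D, D5D, D6D), elongase (Elovl
  families) and peroxisomal β-oxidation (PβOx = 22:6n-3 / 24:6n-3)
  activity.
- **Statistics.** Middle-aged (< 60 y) vs elderly (≥ 60 y) Student or
  Welch t-tests per region with Benjamini–Hochberg FDR control at
  Q = 10%, star coding, and signed percent changes; Spearman
  age-continuum correlations (exact permutation p for small untied
  samples); cross-region Spearman correlation matrices of any index.
- **Synthetic cohorts.** A seeded logistic-normal simulator reproducing
  the mean ± SEM structure of a packaged 13-region × 2-group reference
  table (25 fatty acids per cell), with exact closure, positivity, and
  optional log-linear age trends — so the full pipeline is testable
  without access to raw subject data.

The package is aimed at lipidomics and neurochemistry researchers who
work with FAME/GC fatty-acid tables in mol% and want reproducible index
computation, group comparison and simulation in one place.

## Worked example

```r
library(lipidaging)

# Reference mean composition of the olive (medulla oblongata),
# middle-aged group, from the packaged table:
prof <- table2_profile("olive", "middle_aged")
compute_index_set(prof)
#> # A tibble: 1 x 10
#>     ACL   SFA   UFA  MUFA  PUFA PUFAn3 PUFAn6   DBI    PI SFA_UFA
#> 1  18.4  39.3  60.8  46.6  14.1   2.81   11.3  104.  60.0   0.646

round(estimate_activities(prof)[c("D9D_n9", "D5D_n6", "D6D_n3_b", "PbOx")], 3)
#>   D9D_n9   D5D_n6 D6D_n3_b     PbOx
#>    1.520    2.810    5.444    3.571
```

ACL ≈ 18.4 carbons and DBI ≈ 104 say the olive membrane averages about
18 carbons and one double bond per chain; the unusually low PI ≈ 60
reflects its MUFA-rich, PUFA-poor profile. D6D(b) > D5D is this
region's signature inversion of the usual desaturase ordering.

```r
# A seeded synthetic cohort with the reference 9/8 age structure:
coh <- simulate_cohort(sim_config(
  seed = 1, regions = c("temporal", "cingulate"), ages = table1_ages()
))
cmp <- run_group_comparison(coh)
head(cmp[c("region", "variable", "t_stat", "p_raw", "q_adj",
           "pct_change", "sig_flags")], 4)
#>   region   variable t_stat p_raw q_adj pct_change sig_flags
#> 1 temporal 14:0     -0.333 0.744 0.865      0.633 ""
#> 2 temporal 16:0      0.196 0.847 0.897     -0.335 ""
#> 3 temporal 16:1n-7  -0.701 0.494 0.865      3.80  ""
#> 4 temporal 18:0     -0.776 0.450 0.865      1.13  ""
```

Under this null simulation (both groups drawn from the same template)
no variable survives FDR adjustment, as expected. Use
`age_effect("20:0", 0.01)` in `sim_config()` to inject a log-linear age
trend and `run_age_correlation()` to recover it.

A thin command-line wrapper over the same functions lives at
`inst/cli/lipidaging.R` (subcommands `validate`, `indexes`,
`activities`, `compare`, `correlate`, `simulate`, `report`), writing
tidy CSV outputs plus JSON run manifests.

## Documentation

The methods vignette (`vignettes/brain-fatty-acid-aging.Rmd`) describes
the model, the simulator's noise calibration, numerical choices and
limitations.
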