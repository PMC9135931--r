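# Shared fixtures, built in code.

# A random closed profile over the study panel (Dirichlet-ish via
# normalized gamma draws).
random_profile <- function(concentration = 2) {
  panel <- fa_panel()
  x <- stats::rgamma(nrow(panel), shape = concentration)
  stats::setNames(renormalize(x), panel$canonical)
}

# A tiny two-region cohort built directly from fixture templates plus
# deterministic jitter, with a configurable group structure.
toy_cohort <- function(n = 6, regions = c("olive", "frontal"), seed = 99) {
  simulate_cohort(sim_config(
    seed = seed, regions = regions, n_subjects = n,
    ages = round(seq(40, 80, length.out = n))
  ))
}

# Reference panel constants reused across tests.
panel_names <- fa_panel()$canonical
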