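# Surrogate enzyme activities estimated from product/substrate mol% ratios.
# These are indices of flux through the elongation/desaturation pathway,
# not true enzymatic rates.

#' Built-in product/substrate ratio definitions
#'
#' The 17 standard surrogate activities: 5 desaturase indices (delta-9,
#' delta-5, delta-6), 11 elongase indices (Elovl families) and the
#' peroxisomal beta-oxidation surrogate (PbOx = 22:6n-3 / 24:6n-3, the
#' last step of docosahexaenoate synthesis).
#'
#' @return A tibble with columns `name` (machine-safe identifier),
#'   `label` (conventional typography), `family` (`desaturase`,
#'   `elongase` or `peroxisomal`), `numerator`, `denominator`.
#' @export
builtin_ratio_table <- function() {
  tibble::tribble(
    ~name, ~label, ~family, ~numerator, ~denominator,
    "D9D_n7", "D9D (n-7)", "desaturase", "16:1n-7", "16:0",
    "D9D_n9", "D9D (n-9)", "desaturase", "18:1n-9", "18:0",
    "D5D_n6", "D5D (n-6)", "desaturase", "20:4n-6", "20:3n-6",
    "D6D_n3_a", "D6D (n-3) (a)", "desaturase", "18:4n-3", "18:3n-3",
    "D6D_n3_b", "D6D (n-3) (b)", "desaturase", "24:6n-3", "24:5n-3",
    "Elovl3_n9_a", "Elovl3 (n-9) (a)", "elongase", "20:1n-9", "18:1n-9",
    "Elovl3_n9_b", "Elovl3 (n-9) (b)", "elongase", "22:1n-9", "20:1n-9",
    "Elovl3_n9_c", "Elovl3 (n-9) (c)", "elongase", "24:1n-9", "22:1n-9",
    "Elovl6", "Elovl6", "elongase", "18:0", "16:0",
    "Elovl137_a", "Elovl1-3-7 (a)", "elongase", "20:0", "18:0",
    "Elovl137_b", "Elovl1-3-7 (b)", "elongase", "22:0", "20:0",
    "Elovl137_c", "Elovl1-3-7 (c)", "elongase", "24:0", "22:0",
    "Elovl5_n6", "Elovl5 (n-6)", "elongase", "20:2n-6", "18:2n-6",
    "Elovl25_n6", "Elovl2-5 (n-6)", "elongase", "22:4n-6", "20:4n-6",
    "Elovl25_n3", "Elovl2-5 (n-3)", "elongase", "22:5n-3", "20:5n-3",
    "Elovl2_n3", "Elovl2 (n-3)", "elongase", "24:5n-3", "22:5n-3",
    "PbOx", "PbOx", "peroxisomal", "22:6n-3", "24:6n-3"
  )
}

#' Coerce and validate a custom ratio table
#'
#' @param df Data frame with columns `name`, `numerator`, `denominator`
#'   and optionally `family`, `label`.
#' @param panel Panel the numerators/denominators must belong to.
#' @return A validated ratio tibble usable with [estimate_activities()].
#' @export
as_ratio_table <- function(df, panel = fa_panel()) {
  need <- c("name", "numerator", "denominator")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop("ratio table missing column(s): ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  df <- tibble::as_tibble(df)
  if (!"family" %in% names(df)) df$family <- NA_character_
  if (!"label" %in% names(df)) df$label <- df$name
  df$numerator <- fa_parse(df$numerator)$canonical
  df$denominator <- fa_parse(df$denominator)$canonical
  if (anyDuplicated(df$name)) stop("duplicate ratio names", call. = FALSE)
  if (any(df$numerator == df$denominator)) {
    stop("numerator and denominator must differ", call. = FALSE)
  }
  off <- setdiff(c(df$numerator, df$denominator), panel$canonical)
  if (length(off)) {
    stop("ratio species not in panel: ", paste(off, collapse = ", "),
      call. = FALSE
    )
  }
  df[c("name", "label", "family", "numerator", "denominator")]
}

#' Estimate surrogate activities for one profile
#'
#' Each activity is the mol% ratio of a pathway product to its immediate
#' substrate. A ratio is undefined (`NA`) when the denominator is below
#' `eps`; compositions quantified by gas chromatography bottom out around
#' 0.02 mol%, so real data never reaches the default threshold.
#'
#' @param values Named numeric mol% profile.
#' @param ratios Ratio definitions, default [builtin_ratio_table()].
#' @param eps Denominator threshold below which the ratio is `NA`.
#' @return Named numeric vector, one element per ratio.
#' @examples
#' estimate_activities(table2_profile("olive", "middle_aged"))["D9D_n9"]
#' @export
estimate_activities <- function(values, ratios = builtin_ratio_table(),
                                eps = 1e-6) {
  absent <- setdiff(
    unique(c(ratios$numerator, ratios$denominator)), names(values)
  )
  if (length(absent)) {
    stop(
      "profile lacks species required by ratio table: ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  num <- unname(values[ratios$numerator])
  den <- unname(values[ratios$denominator])
  out <- ifelse(is.na(den) | den < eps, NA_real_, num / den)
  stats::setNames(out, ratios$name)
}

#' Per-subject activities for a whole cohort
#'
#' @param cohort Cohort tibble.
#' @param ratios Ratio definitions, default [builtin_ratio_table()].
#' @param eps Denominator threshold for undefined ratios.
#' @return Tibble: cohort metadata columns followed by one column per
#'   activity.
#' @export
cohort_activities <- function(cohort, ratios = builtin_ratio_table(),
                              eps = 1e-6) {
  m <- cohort_profile_matrix(cohort)
  vals <- purrr::map(seq_len(nrow(ratios)), function(i) {
    num <- m[, ratios$numerator[i]]
    den <- m[, ratios$denominator[i]]
    unname(ifelse(den < eps, NA_real_, num / den))
  })
  names(vals) <- ratios$name
  dplyr::bind_cols(cohort_meta(cohort), tibble::as_tibble(vals))
}
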