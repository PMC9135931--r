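# Membrane composition indexes derived from one mol% profile.
#
# All indexes are linear functionals of the composition except the
# SFA/UFA ratio, so group means of per-subject indexes coincide with the
# index of the group-mean profile for the linear ones.

.pi_weights <- c(0, 0.025, 1, 2, 4, 6, 8) # indexed by double bonds + 1

index_names <- function() {
  c("ACL", "SFA", "UFA", "MUFA", "PUFA", "PUFAn3", "PUFAn6", "DBI", "PI",
    "SFA_UFA")
}

profile_vector <- function(values, panel = fa_panel()) {
  missing <- setdiff(panel$canonical, names(values))
  if (length(missing)) {
    stop(
      "profile is missing panel species: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  x <- values[panel$canonical]
  if (anyNA(x)) {
    stop("profile contains NA mol% values", call. = FALSE)
  }
  unname(x)
}

#' Average chain length
#'
#' `ACL = sum over chain lengths C of (total mol% with C carbons x C) / 100`,
#' grouping by carbon count only, irrespective of unsaturation. On a
#' closed profile this is the mean number of carbon atoms per acyl chain.
#'
#' @param values Named numeric mol% profile covering the panel.
#' @param panel Panel definition, default [fa_panel()].
#' @return Scalar ACL in carbon atoms.
#' @examples
#' compute_acl(table2_profile("olive", "middle_aged"))
#' @export
compute_acl <- function(values, panel = fa_panel()) {
  sum(profile_vector(values, panel) * panel$carbons) / 100
}

#' Double bond index
#'
#' Mol%-weighted double-bond density per 100 chains:
#' `DBI = 1*monoenoic + 2*dienoic + ... + 6*hexaenoic`, equivalently the
#' mol%-weighted sum of double-bond counts.
#'
#' @inheritParams compute_acl
#' @return Scalar DBI (dimensionless).
#' @export
compute_dbi <- function(values, panel = fa_panel()) {
  sum(profile_vector(values, panel) * panel$double_bonds)
}

#' Peroxidizability index
#'
#' Susceptibility of the membrane to lipid peroxidation, weighting each
#' unsaturation class by its relative oxidizability:
#' `PI = 0.025*monoenoic + 1*dienoic + 2*trienoic + 4*tetraenoic +
#' 6*pentaenoic + 8*hexaenoic`. Monoenes are nearly inert; weights rise
#' steeply with the number of bis-allylic positions.
#'
#' @inheritParams compute_acl
#' @return Scalar PI (dimensionless).
#' @export
compute_pi <- function(values, panel = fa_panel()) {
  sum(profile_vector(values, panel) * .pi_weights[panel$double_bonds + 1])
}

#' Saturation class totals
#'
#' Sums mol% by unsaturation class: SFA (0 double bonds), MUFA (1), PUFA
#' (2 or more, split into the n-3 and n-6 series), UFA = MUFA + PUFA, and
#' the SFA/UFA ratio (`NA` when UFA is zero).
#'
#' @inheritParams compute_acl
#' @return One-row tibble with columns `SFA`, `UFA`, `MUFA`, `PUFA`,
#'   `PUFAn3`, `PUFAn6`, `SFA_UFA`.
#' @export
compute_class_totals <- function(values, panel = fa_panel()) {
  x <- profile_vector(values, panel)
  db <- panel$double_bonds
  sfa <- sum(x[db == 0])
  mufa <- sum(x[db == 1])
  pufa <- sum(x[db >= 2])
  ufa <- mufa + pufa
  tibble::tibble(
    SFA = sfa, UFA = ufa, MUFA = mufa, PUFA = pufa,
    PUFAn3 = sum(x[db >= 2 & panel$series == "n-3"]),
    PUFAn6 = sum(x[db >= 2 & panel$series == "n-6"]),
    SFA_UFA = ifelse(ufa > 0, sfa / ufa, NA_real_)
  )
}

#' Full index set for one profile
#'
#' Bundles [compute_acl()], [compute_class_totals()], [compute_dbi()] and
#' [compute_pi()] into one row.
#'
#' @inheritParams compute_acl
#' @return One-row tibble: `ACL`, `SFA`, `UFA`, `MUFA`, `PUFA`, `PUFAn3`,
#'   `PUFAn6`, `DBI`, `PI`, `SFA_UFA`.
#' @export
compute_index_set <- function(values, panel = fa_panel()) {
  ct <- compute_class_totals(values, panel)
  tibble::tibble(
    ACL = compute_acl(values, panel),
    SFA = ct$SFA, UFA = ct$UFA, MUFA = ct$MUFA, PUFA = ct$PUFA,
    PUFAn3 = ct$PUFAn3, PUFAn6 = ct$PUFAn6,
    DBI = compute_dbi(values, panel),
    PI = compute_pi(values, panel),
    SFA_UFA = ct$SFA_UFA
  )
}

#' Per-subject indexes for a whole cohort
#'
#' Vectorized [compute_index_set()] over all rows of a cohort.
#'
#' @param cohort Cohort tibble (see [read_cohort()]).
#' @param panel Panel definition, default [fa_panel()].
#' @return Tibble: cohort metadata columns followed by the index columns.
#' @export
cohort_indexes <- function(cohort, panel = fa_panel()) {
  m <- cohort_profile_matrix(cohort, panel)
  db <- panel$double_bonds
  sfa <- rowSums(m[, db == 0, drop = FALSE])
  mufa <- rowSums(m[, db == 1, drop = FALSE])
  pufa <- rowSums(m[, db >= 2, drop = FALSE])
  ufa <- mufa + pufa
  out <- tibble::tibble(
    ACL = as.numeric(m %*% panel$carbons) / 100,
    SFA = sfa, UFA = ufa, MUFA = mufa, PUFA = pufa,
    PUFAn3 = rowSums(m[, db >= 2 & panel$series == "n-3", drop = FALSE]),
    PUFAn6 = rowSums(m[, db >= 2 & panel$series == "n-6", drop = FALSE]),
    DBI = as.numeric(m %*% db),
    PI = as.numeric(m %*% .pi_weights[db + 1]),
    SFA_UFA = ifelse(ufa > 0, sfa / ufa, NA_real_)
  )
  dplyr::bind_cols(cohort_meta(cohort), out)
}
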