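# Cohort-level analyses: middle-aged vs elderly comparison per region,
# age-continuum correlation, and cross-region correlation matrices.

# Per-subject variable table for a family of variables:
#   "profile"    = 25 fatty acids + 10 indexes + PbOx  (the main table)
#   "activities" = the 17 surrogate activities         (its own BH family)
comparison_variables <- function(cohort,
                                 family = c("profile", "activities")) {
  family <- match.arg(family)
  if (family == "profile") {
    idx <- cohort_indexes(cohort)
    act <- cohort_activities(cohort)
    dplyr::bind_cols(
      cohort_meta(cohort),
      cohort[fa_panel()$canonical],
      idx[index_names()],
      act["PbOx"]
    )
  } else {
    cohort_activities(cohort)
  }
}

#' Middle-aged vs elderly comparison across regions
#'
#' For each region, compares every variable of the chosen family between
#' the two age groups: group means, SEMs and sizes, a two-sided t-test,
#' the signed percent change of the elderly group relative to the
#' middle-aged baseline, pre-FDR star coding from the raw p-value, and
#' Benjamini-Hochberg q-values adjusted within the region (each region's
#' variable family is one multiple-testing family, mirroring how the
#' per-region result tables are organized).
#'
#' @param cohort Cohort tibble spanning both age groups.
#' @param config A [comparison_config()].
#' @param family `"profile"` (fatty acids + indexes + PbOx) or
#'   `"activities"` (the 17 surrogate activities).
#' @return Tibble with one row per region x variable: `region`,
#'   `variable`, `mean_mid`, `sem_mid`, `n_mid`, `mean_eld`, `sem_eld`,
#'   `n_eld`, `t_stat`, `p_raw`, `q_adj`, `discovery`, `pct_change`,
#'   `sig_flags`. Regions lacking one of the groups are skipped with a
#'   warning.
#' @export
run_group_comparison <- function(cohort, config = comparison_config(),
                                 family = c("profile", "activities")) {
  family <- match.arg(family)
  vars <- comparison_variables(cohort, family)
  var_names <- setdiff(names(vars), .meta_cols)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  out <- purrr::map(unique(vars$region), function(rg) {
    sub <- vars[vars$region == rg, ]
    grp <- suppressWarnings(split_age_groups(sub, config$age_cut))
    if (nrow(grp$middle_aged) < 2 || nrow(grp$elderly) < 2) {
      warning(
        sprintf("region '%s': a group has fewer than 2 subjects; skipped", rg),
        call. = FALSE
      )
      return(NULL)
    }
    rows <- purrr::map(var_names, function(v) {
      x <- grp$middle_aged[[v]]
      y <- grp$elderly[[v]]
      x <- x[!is.na(x)]
      y <- y[!is.na(y)]
      tt <- if (length(x) >= 2 && length(y) >= 2) {
        t_test_two_sample(x, y, config$t_variant)
      } else {
        list(t_stat = NA_real_, df = NA_real_, p = NA_real_)
      }
      tibble::tibble(
        region = rg, variable = v,
        mean_mid = mean(x), sem_mid = sem(x), n_mid = length(x),
        mean_eld = mean(y), sem_eld = sem(y), n_eld = length(y),
        t_stat = tt$t_stat, p_raw = tt$p,
        pct_change = percent_change(mean(x), mean(y)),
        sig_flags = sig_stars(tt$p)
      )
    })
    res <- dplyr::bind_rows(rows)
    adj <- bh_adjust(res$p_raw, config$Q)
    res$q_adj <- adj$q
    res$discovery <- adj$discovery
    res
  })
  cols <- c(
    "region", "variable", "mean_mid", "sem_mid", "n_mid",
    "mean_eld", "sem_eld", "n_eld", "t_stat", "p_raw", "q_adj",
    "discovery", "pct_change", "sig_flags"
  )
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      region = character(), variable = character(),
      mean_mid = double(), sem_mid = double(), n_mid = integer(),
      mean_eld = double(), sem_eld = double(), n_eld = integer(),
      t_stat = double(), p_raw = double(), q_adj = double(),
      discovery = logical(), pct_change = double(), sig_flags = character()
    )
  }
  out[cols]
}

#' Age-continuum Spearman correlation across regions
#'
#' Treats age as a continuous variable: for each region and variable of
#' the chosen family, Spearman's rank correlation of the variable with
#' age, with BH q-values adjusted within the region.
#'
#' @inheritParams run_group_comparison
#' @param Q Maximum discovery rate for the BH adjustment.
#' @param method Passed to [spearman_age()].
#' @return Tibble: `region`, `variable`, `rho`, `p_raw`, `q_adj`,
#'   `discovery`, `n`.
#' @export
run_age_correlation <- function(cohort, family = c("profile", "activities"),
                                Q = 0.10, method = "auto") {
  family <- match.arg(family)
  vars <- comparison_variables(cohort, family)
  var_names <- setdiff(names(vars), .meta_cols)
  out <- purrr::map(unique(vars$region), function(rg) {
    sub <- vars[vars$region == rg, ]
    rows <- purrr::map(var_names, function(v) {
      sp <- spearman_age(sub[[v]], sub$age, method = method)
      tibble::tibble(
        region = rg, variable = v, rho = sp$rho, p_raw = sp$p, n = sp$n
      )
    })
    res <- dplyr::bind_rows(rows)
    adj <- bh_adjust(res$p_raw, Q)
    res$q_adj <- adj$q
    res$discovery <- adj$discovery
    res
  })
  dplyr::bind_rows(out)[c(
    "region", "variable", "rho", "p_raw", "q_adj", "discovery", "n"
  )]
}

#' Cross-region correlation matrix for one index
#'
#' Spearman correlation of one per-subject index between every pair of
#' regions, with subjects matched by `subject_id` and pairwise-complete
#' deletion. A pair with fewer than `min_n` shared subjects is undefined.
#'
#' @param cohort Cohort tibble with subjects shared across regions.
#' @param index One of the index names (`"ACL"`, `"SFA"`, ..., `"PI"`,
#'   `"SFA_UFA"`) or `"PbOx"`.
#' @param alpha Significance level for the `sig` mask.
#' @param min_n Minimum shared subjects per pair (default 3).
#' @return Object of class `"region_correlation"`: list with symmetric
#'   matrices `rho`, `p`, `n`, logical `sig`, plus `index` and `alpha`.
#' @export
correlation_matrix <- function(cohort, index = "PUFAn6", alpha = 0.05,
                               min_n = 3) {
  vars <- comparison_variables(cohort, "profile")
  if (!index %in% setdiff(names(vars), .meta_cols)) {
    stop("unknown index '", index, "'", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    vars[c("subject_id", "region", index)],
    names_from = "region", values_from = dplyr::all_of(index)
  )
  regions <- intersect(brain_regions(), names(wide))
  k <- length(regions)
  rho <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  pmat <- rho
  nmat <- matrix(0L, k, k, dimnames = list(regions, regions))
  diag(rho) <- 1
  diag(pmat) <- 0
  for (i in seq_len(k)) {
    nmat[i, i] <- sum(!is.na(wide[[regions[i]]]))
    for (j in seq_len(k)[-seq_len(i)]) {
      xi <- wide[[regions[i]]]
      xj <- wide[[regions[j]]]
      keep <- stats::complete.cases(xi, xj)
      nmat[i, j] <- nmat[j, i] <- sum(keep)
      if (sum(keep) < min_n) next
      sp <- spearman_age(xi[keep], xj[keep], method = "approx")
      rho[i, j] <- rho[j, i] <- sp$rho
      pmat[i, j] <- pmat[j, i] <- sp$p
    }
  }
  structure(
    list(
      rho = rho, p = pmat, n = nmat, sig = !is.na(pmat) & pmat <= alpha,
      index = index, alpha = alpha
    ),
    class = "region_correlation"
  )
}

#' @export
print.region_correlation <- function(x, ...) {
  k <- nrow(x$rho)
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf(
    "cross-region Spearman matrix for %s: %d regions, %d/%d significant pairs at alpha = %.2f\n",
    x$index, k, sum(x$sig[upper.tri(x$sig)], na.rm = TRUE),
    sum(!is.na(off)), x$alpha
  ))
  invisible(x)
}
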