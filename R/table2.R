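# Packaged reference table: per-region group means and SEMs of the
# 25-species panel plus the printed indexes, middle-aged (< 60 y, n = 9)
# vs elderly (>= 60 y, n = 8) healthy donors, transcribed cell by cell
# from the published regional table. Star coding and the FDR-adjusted
# significance column are carried along as printed.

.table2_env <- new.env(parent = emptyenv())

#' Reference region templates (means and SEMs)
#'
#' Returns the transcribed reference table in long form: for each of the
#' 13 regions, the middle-aged and elderly group mean and SEM of every
#' panel fatty acid and of each derived index (ACL, class totals, DBI,
#' PI, SFA/UFA ratio and the PbOx activity surrogate), together with the
#' printed pre-FDR star coding and FDR-adjusted significance column.
#'
#' @return Tibble with columns `region`, `variable`, `mean_mid`,
#'   `sem_mid`, `mean_eld`, `sem_eld`, `stars`, `sig_fdr`.
#' @export
table2_templates <- function() {
  if (is.null(.table2_env$tbl)) {
    path <- system.file("extdata", "table2_templates.csv",
      package = "lipidaging", mustWork = TRUE
    )
    .table2_env$tbl <- readr::read_csv(
      path,
      col_types = readr::cols(
        region = readr::col_character(),
        variable = readr::col_character(),
        stars = readr::col_character(),
        .default = readr::col_double()
      ),
      progress = FALSE
    )
  }
  tbl <- .table2_env$tbl
  tbl$stars[is.na(tbl$stars)] <- ""
  tbl
}

table2_group_col <- function(group) {
  group <- match.arg(group, c("middle_aged", "elderly"))
  if (group == "middle_aged") "mid" else "eld"
}

#' Reference group-mean composition profile
#'
#' The 25 printed fatty-acid group means for one region and age group,
#' as a profile vector.
#'
#' @param region One of [brain_regions()].
#' @param group `"middle_aged"` or `"elderly"`.
#' @return Named numeric vector of 25 mol% means (as printed; closure
#'   holds to within about 0.03 mol% because of table rounding).
#' @export
table2_profile <- function(region, group = c("middle_aged", "elderly")) {
  region <- match.arg(region, brain_regions())
  col <- paste0("mean_", table2_group_col(match.arg(group)))
  tbl <- table2_templates()
  tbl <- tbl[tbl$region == region & tbl$variable %in% fa_panel()$canonical, ]
  stats::setNames(tbl[[col]], tbl$variable)
}

#' Reference printed index values
#'
#' @inheritParams table2_profile
#' @return Named numeric vector of printed index values (`ACL`, `SFA`,
#'   ..., `PI`, `SFA_UFA`, `PbOx`) for the region and group.
#' @export
table2_indexes <- function(region, group = c("middle_aged", "elderly")) {
  region <- match.arg(region, brain_regions())
  col <- paste0("mean_", table2_group_col(match.arg(group)))
  tbl <- table2_templates()
  tbl <- tbl[tbl$region == region & !tbl$variable %in% fa_panel()$canonical, ]
  stats::setNames(tbl[[col]], tbl$variable)
}

#' Reference mean profiles as a cohort
#'
#' Builds a pseudo-cohort of the 26 region-by-group mean profiles. Useful
#' for exercising the pipeline against the reference table; ages are
#' nominal group midpoints (50 and 70 years), not real subjects.
#'
#' @return Cohort tibble with 26 rows.
#' @export
table2_cohort <- function() {
  rows <- purrr::map(brain_regions(), function(rg) {
    purrr::map(c("middle_aged", "elderly"), function(gr) {
      prof <- table2_profile(rg, gr)
      dplyr::bind_cols(
        tibble::tibble(
          subject_id = paste(rg, gr, sep = "."),
          region = rg,
          age = if (gr == "middle_aged") 50 else 70,
          sex = "unknown", pmt_hours = NA_real_
        ),
        tibble::as_tibble(as.list(prof))
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Build a simulation template from the reference table
#'
#' Extracts the per-species mean and SEM for one region and age group,
#' renormalizes the means to exact closure, and floors the SEM at
#' `sem_floor` (printed SEMs are rounded to two decimals, so a printed
#' "0.00" means "below 0.005", not zero).
#'
#' @inheritParams table2_profile
#' @param n Number of subjects behind the template; defaults to the
#'   study's 9 (middle-aged) or 8 (elderly). Override per region when a
#'   different per-region sample size is known.
#' @param sem_floor Lower bound applied to printed SEMs (mol%).
#' @return An object of class `"region_template"`: list with `region`,
#'   `group`, `mean` (closed), `sem`, `n`.
#' @export
template_from_fixture <- function(region,
                                  group = c("middle_aged", "elderly"),
                                  n = NULL, sem_floor = 0.005) {
  region <- match.arg(region, brain_regions())
  group <- match.arg(group)
  gcol <- table2_group_col(group)
  tbl <- table2_templates()
  tbl <- tbl[tbl$region == region & tbl$variable %in% fa_panel()$canonical, ]
  if (is.null(n)) n <- if (group == "middle_aged") 9L else 8L
  structure(
    list(
      region = region, group = group,
      mean = renormalize(
        stats::setNames(tbl[[paste0("mean_", gcol)]], tbl$variable)
      ),
      sem = stats::setNames(
        pmax(tbl[[paste0("sem_", gcol)]], sem_floor), tbl$variable
      ),
      n = as.integer(n)
    ),
    class = "region_template"
  )
}

#' @export
print.region_template <- function(x, ...) {
  cat(sprintf(
    "region template: %s / %s (n = %d), %d species, top species %s = %.2f mol%%\n",
    x$region, x$group, x$n, length(x$mean),
    names(which.max(x$mean)), max(x$mean)
  ))
  invisible(x)
}
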