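# Fatty-acid nomenclature, the study panel, and the cohort data model.
#
# A "profile" throughout the package is a named numeric vector of mol%
# values, names being canonical fatty-acid strings ("16:0", "22:6n-3").
# A "cohort" is a wide tibble: one row per subject x region with metadata
# columns (subject_id, region, age, sex, pmt_hours) and one column per
# panel fatty acid.

.fa_pattern <- "^([0-9]{1,2}):([0-9])(?:n-?([0-9]))?$"

# The 25-species gas-chromatography panel, in table order.
.panel_names <- c(
  "14:0", "16:0", "16:1n-7", "18:0", "18:1n-9", "18:1n-7", "18:2n-6",
  "18:3n-3", "18:4n-3", "20:0", "20:1n-9", "20:2n-6", "20:3n-6", "20:4n-6",
  "20:5n-3", "22:0", "22:1n-9", "22:4n-6", "22:5n-6", "22:5n-3", "22:6n-3",
  "24:0", "24:1n-9", "24:5n-3", "24:6n-3"
)

.meta_cols <- c("subject_id", "region", "age", "sex", "pmt_hours")

#' Parse fatty-acid shorthand names
#'
#' Parses names of the form `"C:D"` (saturated) or `"C:Dn-S"` /
#' `"C:DnS"` (unsaturated), where `C` is the carbon count, `D` the number
#' of double bonds and `S` the series (position of the terminal double
#' bond counted from the methyl end). Both the hyphenated (`"22:6n-3"`)
#' and compact (`"22:6n3"`) dialects are accepted; canonical output is
#' hyphenated.
#'
#' @param names Character vector of fatty-acid names.
#' @return A tibble with columns `name` (input), `carbons`,
#'   `double_bonds`, `series` (`"n-3"`, `"n-6"`, `"n-7"`, `"n-9"` or
#'   `"saturated"`) and `canonical`.
#' @examples
#' fa_parse(c("22:6n3", "16:0", "18:1n-9"))
#' @export
fa_parse <- function(names) {
  if (!is.character(names) || length(names) == 0) {
    stop("`names` must be a non-empty character vector", call. = FALSE)
  }
  m <- regmatches(trimws(names), regexec(.fa_pattern, trimws(names)))
  rows <- purrr::map2(names, m, function(nm, g) {
    if (length(g) == 0) {
      stop(sprintf("cannot parse fatty acid name '%s'", nm), call. = FALSE)
    }
    carbons <- as.integer(g[2])
    db <- as.integer(g[3])
    series_tok <- g[4]
    if (carbons < 12 || carbons > 26 || carbons %% 2 != 0) {
      stop(sprintf(
        "fatty acid '%s': carbon count %d outside the even 12-26 grammar",
        nm, carbons
      ), call. = FALSE)
    }
    if (db > 6) {
      stop(sprintf("fatty acid '%s': %d double bonds exceeds 6", nm, db),
        call. = FALSE
      )
    }
    if (db == 0 && nzchar(series_tok)) {
      stop(sprintf(
        "fatty acid '%s': saturated species must not carry a series token '%s'",
        nm, series_tok
      ), call. = FALSE)
    }
    if (db > 0 && !nzchar(series_tok)) {
      stop(sprintf(
        "fatty acid '%s': unsaturated species requires a series token (n3/n6/n7/n9)",
        nm
      ), call. = FALSE)
    }
    if (nzchar(series_tok) && !series_tok %in% c("3", "6", "7", "9")) {
      stop(sprintf(
        "fatty acid '%s': series token 'n%s' not one of n3, n6, n7, n9",
        nm, series_tok
      ), call. = FALSE)
    }
    series <- if (db == 0) "saturated" else paste0("n-", series_tok)
    tibble::tibble(
      name = nm, carbons = carbons, double_bonds = db, series = series,
      canonical = fa_format(carbons, db, series)
    )
  })
  dplyr::bind_rows(rows)
}

#' Format a fatty acid in canonical notation
#'
#' Inverse of [fa_parse()]: `"C:0"` for saturated species, `"C:Dn-S"`
#' otherwise.
#'
#' @param carbons,double_bonds Integer vectors.
#' @param series Series labels as returned by [fa_parse()].
#' @return Character vector of canonical names.
#' @export
fa_format <- function(carbons, double_bonds, series) {
  ifelse(
    double_bonds == 0,
    sprintf("%d:0", carbons),
    sprintf("%d:%d%s", carbons, double_bonds, series)
  )
}

#' Classify fatty acids by unsaturation
#'
#' @param names Character vector of fatty-acid names (either dialect).
#' @return Character vector: `"SFA"` (no double bond), `"MUFA"` (one) or
#'   `"PUFA"` (two or more). The series of a PUFA is available from
#'   [fa_parse()].
#' @examples
#' fa_classify(c("18:1n-7", "20:4n-6", "24:0"))
#' @export
fa_classify <- function(names) {
  db <- fa_parse(names)$double_bonds
  dplyr::case_when(db == 0 ~ "SFA", db == 1 ~ "MUFA", TRUE ~ "PUFA")
}

#' The 25-species study panel
#'
#' @return A tibble with one row per panel fatty acid (`canonical`,
#'   `carbons`, `double_bonds`, `series`, `class`), in stable table order.
#' @export
fa_panel <- function() {
  p <- fa_parse(.panel_names)
  tibble::tibble(
    canonical = p$canonical,
    carbons = p$carbons,
    double_bonds = p$double_bonds,
    series = p$series,
    class = fa_classify(p$canonical)
  )
}

#' Brain region vocabulary
#'
#' The 13 gray-matter regions covered by the analysis, as machine-safe
#' codes with their anatomical names and developmental division.
#'
#' @param anatomy If `TRUE`, return the full tibble; otherwise just the
#'   character vector of region codes.
#' @return Character vector of codes, or a tibble with columns `region`,
#'   `anatomy`, `division`.
#' @export
brain_regions <- function(anatomy = FALSE) {
  tbl <- tibble::tribble(
    ~region, ~anatomy, ~division,
    "olive", "olive (medulla oblongata)", "hindbrain",
    "vermis", "upper vermis (cerebellum)", "hindbrain",
    "substantia_nigra", "substantia nigra", "midbrain",
    "thalamus", "thalamus", "diencephalon",
    "hippocampus", "hippocampus", "subcortical telencephalon",
    "caudate", "head of the caudate nucleus", "subcortical telencephalon",
    "putamen", "anterior putamen", "subcortical telencephalon",
    "occipital", "occipital cortex areas 17-18", "cortical telencephalon",
    "parietal", "parietal cortex area 7", "cortical telencephalon",
    "temporal", "inferior temporal cortex area 20", "cortical telencephalon",
    "entorhinal", "entorhinal cortex", "cortical telencephalon",
    "frontal", "frontal cortex area 8", "cortical telencephalon",
    "cingulate", "cingulate gyrus area 24", "cortical telencephalon"
  )
  if (anatomy) tbl else tbl$region
}

#' Validate a composition profile
#'
#' Checks the structural facts of a mol% composition: every panel species
#' present, no negative entries, and closure (the values sum to 100 within
#' a tolerance). Missing species are distinct from zero values: a species
#' not measured cannot be silently treated as absent without biasing the
#' chain-length and unsaturation indexes.
#'
#' @param values Named numeric vector of mol% values.
#' @param panel Panel definition tibble, default [fa_panel()].
#' @param tol Closure tolerance in mol% (default 1.0).
#' @return An object of class `"profile_validation"`: a list with
#'   `valid`, `total`, `deviation`, `negative` (names), `missing` (names).
#' @export
validate_profile <- function(values, panel = fa_panel(), tol = 1.0) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  missing <- setdiff(panel$canonical, names(values))
  present <- intersect(names(values), panel$canonical)
  x <- values[present]
  negative <- present[!is.na(x) & x < 0]
  total <- sum(x, na.rm = TRUE)
  deviation <- abs(total - 100)
  structure(
    list(
      valid = length(missing) == 0 && length(negative) == 0 &&
        !anyNA(x) && deviation <= tol,
      total = total, deviation = deviation,
      negative = negative, missing = missing, tol = tol
    ),
    class = "profile_validation"
  )
}

#' @export
print.profile_validation <- function(x, ...) {
  cat(sprintf(
    "composition profile: %s (sum = %.3f mol%%, deviation %.3f, tol %.2f)\n",
    if (x$valid) "valid" else "INVALID", x$total, x$deviation, x$tol
  ))
  if (length(x$negative)) {
    cat("  negative entries:", paste(x$negative, collapse = ", "), "\n")
  }
  if (length(x$missing)) {
    cat("  missing panel species:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Renormalize a profile to exact closure
#'
#' Rescales all values by `100 / sum(values)` so the composition sums to
#' exactly 100 mol%, preserving all ratios between species.
#'
#' @param values Named (or plain) nonnegative numeric vector.
#' @param target Closure total, default 100.
#' @return Rescaled vector of the same shape.
#' @export
renormalize <- function(values, target = 100) {
  s <- sum(values)
  if (!is.finite(s) || s <= 0) {
    stop("cannot renormalize a profile with non-positive total", call. = FALSE)
  }
  values * target / s
}

# --- cohort I/O ---------------------------------------------------------

is_fa_name <- function(x) {
  grepl(.fa_pattern, trimws(x))
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a cohort table
#'
#' Reads a wide CSV/TSV file with one row per subject x region: mandatory
#' metadata columns `subject_id`, `region`, `age` (optional `sex`,
#' `pmt_hours`), and one column per fatty acid. Fatty-acid column headers
#' may use either naming dialect; they are canonicalized on read. Columns
#' that are neither metadata nor parseable fatty-acid names are preserved
#' untouched.
#'
#' @param path File path.
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return A cohort tibble.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, delim = NULL) {
  delim <- infer_delim(path, delim)
  df <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    name_repair = "minimal", comment = "#"
  )
  if (nrow(df) == 0) stop("no data rows in '", path, "'", call. = FALSE)
  mandatory <- c("subject_id", "region", "age")
  absent <- setdiff(mandatory, names(df))
  if (length(absent)) {
    stop(
      "missing mandatory column(s): ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  bad_region <- setdiff(unique(df$region), brain_regions())
  if (length(bad_region)) {
    stop(
      "unknown region code(s): ", paste(bad_region, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(df$age) | df$age <= 0)) {
    stop("ages must be positive", call. = FALSE)
  }
  if (anyDuplicated(df[c("subject_id", "region")])) {
    stop("duplicate (subject_id, region) pairs", call. = FALSE)
  }
  if (!"sex" %in% names(df)) df$sex <- "unknown"
  if (!"pmt_hours" %in% names(df)) df$pmt_hours <- NA_real_
  fa_cols <- setdiff(names(df), .meta_cols)
  fa_cols <- fa_cols[is_fa_name(fa_cols)]
  if (length(fa_cols)) {
    names(df)[match(fa_cols, names(df))] <- fa_parse(fa_cols)$canonical
  }
  panel_cols <- intersect(fa_panel()$canonical, names(df))
  extra <- setdiff(names(df), c(.meta_cols, panel_cols))
  tibble::as_tibble(df)[c(.meta_cols, panel_cols, extra)]
}

#' Write a cohort table
#'
#' @param cohort Cohort tibble.
#' @param path Output path; `.tsv`/`.tab` extensions select tab delimiting.
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = NULL) {
  delim <- infer_delim(path, delim)
  readr::write_delim(cohort, path, delim = delim, progress = FALSE)
  invisible(path)
}

# Extract the subject x species mol% matrix (panel order) from a cohort.
# Missing species or NA values abort: indexes on partial profiles would
# be silently biased.
cohort_profile_matrix <- function(cohort, panel = fa_panel()) {
  missing <- setdiff(panel$canonical, names(cohort))
  if (length(missing)) {
    stop(
      "cohort is missing panel species: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(cohort[panel$canonical])
  if (!is.numeric(m)) stop("fatty-acid columns must be numeric", call. = FALSE)
  if (anyNA(m)) {
    stop(
      "NA mol% values present; impute explicitly before computing indexes",
      call. = FALSE
    )
  }
  rownames(m) <- paste(cohort$subject_id, cohort$region, sep = ":")
  m
}

cohort_meta <- function(cohort) {
  cohort[intersect(.meta_cols, names(cohort))]
}
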