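# Statistical engine: group tests, percent change, BH-FDR, Spearman
# rank correlation (with exact small-sample permutation p).

#' Comparison configuration
#'
#' @param age_cut Age boundary in years; subjects with `age < age_cut`
#'   are middle-aged, `age >= age_cut` elderly (the source cohort has no
#'   subject aged exactly 60, so the boundary convention is free; ties go
#'   to the elderly group).
#' @param alpha Per-test significance level for star coding.
#' @param Q Maximum false discovery rate for BH adjustment.
#' @param t_variant `"student_pooled"` (pooled-variance Student t, the
#'   default) or `"welch"`.
#' @return A list of class `"comparison_config"`.
#' @export
comparison_config <- function(age_cut = 60, alpha = 0.05, Q = 0.10,
                              t_variant = c("student_pooled", "welch")) {
  stopifnot(alpha > 0, alpha < 1, Q > 0, Q < 1, age_cut > 0)
  structure(
    list(
      age_cut = age_cut, alpha = alpha, Q = Q,
      t_variant = match.arg(t_variant)
    ),
    class = "comparison_config"
  )
}

#' Split a cohort into age groups
#'
#' @param cohort Cohort tibble with an `age` column.
#' @param age_cut Boundary in years (default 60). `age < age_cut` is
#'   middle-aged; `age >= age_cut` is elderly.
#' @return Named list `middle_aged` / `elderly` of cohort subsets. An
#'   empty group triggers a warning (downstream tests are undefined).
#' @export
split_age_groups <- function(cohort, age_cut = 60) {
  out <- list(
    middle_aged = dplyr::filter(cohort, .data$age < age_cut),
    elderly = dplyr::filter(cohort, .data$age >= age_cut)
  )
  empty <- names(out)[vapply(out, nrow, 0L) == 0]
  if (length(empty)) {
    warning("empty age group(s): ", paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Star coding for p-values
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.01, `"***"` for p < 0.001;
#' empty string otherwise (including `NA`).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
sig_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Two-sample t-test
#'
#' Two-sided t-test between two groups of observations, either with
#' pooled variance (Student, df = n1 + n2 - 2) or Welch-Satterthwaite df.
#' Zero variance in both groups makes the statistic undefined; this is
#' reported as `NA` rather than an error.
#'
#' @param x,y Numeric vectors (each of length >= 2 after NA removal).
#' @param t_variant `"student_pooled"` or `"welch"`.
#' @return List with `t_stat`, `df`, `p`.
#' @export
t_test_two_sample <- function(x, y,
                              t_variant = c("student_pooled", "welch")) {
  t_variant <- match.arg(t_variant)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(t_stat = NA_real_, df = NA_real_, p = NA_real_))
  }
  ht <- stats::t.test(x, y, var.equal = t_variant == "student_pooled")
  list(
    t_stat = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value
  )
}

#' Two-sample t-test from summary statistics
#'
#' Reconstructs a two-sided t-test from printed group means, SEMs and
#' sample sizes; lets users sanity-check published star coding when raw
#' data are unavailable. The Welch variant works directly on the SEMs;
#' the Student variant reconstructs SDs as `sem * sqrt(n)` and pools.
#' The statistic is signed as group 2 minus group 1.
#'
#' @param mean1,sem1,n1 First group (e.g. middle-aged) summary.
#' @param mean2,sem2,n2 Second group (e.g. elderly) summary.
#' @param t_variant `"welch"` (default here) or `"student_pooled"`.
#' @return Tibble with columns `t_stat`, `df`, `p` (vectorized).
#' @export
t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2,
                           t_variant = c("welch", "student_pooled")) {
  t_variant <- match.arg(t_variant)
  stopifnot(all(n1 >= 2), all(n2 >= 2), all(sem1 > 0 | sem2 > 0))
  if (t_variant == "welch") {
    se2 <- sem1^2 + sem2^2
    t_stat <- (mean2 - mean1) / sqrt(se2)
    df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  } else {
    sd1 <- sem1 * sqrt(n1)
    sd2 <- sem2 * sqrt(n2)
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t_stat <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tibble::tibble(
    t_stat = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df)
  )
}

#' Signed percent change between group means
#'
#' `100 * (mean_eld - mean_mid) / mean_mid`: the elderly group relative
#' to the middle-aged baseline. Undefined (`NA`) when the baseline is
#' not positive.
#'
#' @param mean_mid,mean_eld Numeric vectors of group means.
#' @return Numeric vector of signed percentages.
#' @examples
#' percent_change(1.84, 1.29) # about -30
#' @export
percent_change <- function(mean_mid, mean_eld) {
  ifelse(mean_mid > 0, 100 * (mean_eld - mean_mid) / mean_mid, NA_real_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (`q`) and the discovery set at
#' maximum discovery rate `Q`. Input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @param Q Maximum discovery rate (default 0.10).
#' @return Tibble with columns `p`, `q`, `discovery`.
#' @export
bh_adjust <- function(p, Q = 0.10) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, discovery = !is.na(q) & q <= Q)
}

# All permutations of 1..n as an (n! x n) matrix.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutations_of(n - 1)
  p <- nrow(sub)
  out <- matrix(0L, n * p, n)
  for (i in seq_len(n)) {
    out[(i - 1) * p + seq_len(p), ] <- cbind(i, sub + (sub >= i))
  }
  out
}

#' Spearman rank correlation against age
#'
#' Rank correlation on average-ranked data. The p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom; for untied samples of n <= 9 an exact two-sided
#' permutation p over all `n!` rank orders is used instead (selectable
#' via `method`).
#'
#' @param x Numeric variable values.
#' @param age Numeric ages, paired with `x`.
#' @param method `"auto"` (exact when n <= 9 and untied), `"exact"` or
#'   `"approx"`.
#' @return List with `rho`, `p`, `n`, `method` (`rho` and `p` are `NA`
#'   when either variable is constant).
#' @export
spearman_age <- function(x, age, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, age)
  x <- x[keep]
  age <- age[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  rho <- suppressWarnings(stats::cor(x, age, method = "spearman"))
  if (is.na(rho)) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(age) > 0
  if (method == "exact" && ties) {
    stop("exact permutation p requires untied data", call. = FALSE)
  }
  use_exact <- method == "exact" || (method == "auto" && n <= 9 && !ties)
  if (use_exact) {
    rx <- rank(x)
    ry <- rank(age)
    perms <- permutations_of(n)
    # untied ranks: rho = 1 - 6 sum(d^2) / (n (n^2 - 1))
    d2 <- rowSums((matrix(rx, nrow(perms), n, byrow = TRUE) -
      matrix(ry[perms], nrow(perms), n))^2)
    rhos <- 1 - 6 * d2 / (n * (n^2 - 1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  list(rho = rho, p = p, n = n, method = "approx")
}
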