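# Statistical engine oracles and properties.

closed_form_t <- function(x, y, pooled = TRUE) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

test_that("two-sample t matches the closed-form textbook oracle to 1e-10", {
  set.seed(41)
  for (i in 1:30) {
    x <- stats::rnorm(sample(3:12, 1), mean = stats::runif(1, -2, 2))
    y <- stats::rnorm(sample(3:12, 1), sd = stats::runif(1, 0.5, 2))
    for (pooled in c(TRUE, FALSE)) {
      variant <- if (pooled) "student_pooled" else "welch"
      got <- t_test_two_sample(x, y, variant)
      want <- closed_form_t(x, y, pooled)
      expect_equal(got$t_stat, want$t, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
  }
})

test_that("degenerate t inputs behave as documented", {
  expect_equal(t_test_two_sample(c(1, 2, 3), c(1, 2, 3))$t_stat, 0)
  expect_equal(t_test_two_sample(c(1, 2, 3), c(1, 2, 3))$p, 1)
  big <- t_test_two_sample(c(1, 2, 3), c(100.1, 100.2, 99.9))
  expect_lt(big$p, 0.001)
  const <- t_test_two_sample(rep(1, 3), rep(1, 4))
  expect_true(is.na(const$p))
  expect_error(t_test_two_sample(1, c(1, 2)), "at least 2")
})

test_that("t statistics are invariant under common affine transforms", {
  set.seed(43)
  x <- stats::rnorm(8); y <- stats::rnorm(9, 1)
  base <- t_test_two_sample(x, y)
  shifted <- t_test_two_sample(3 * x - 7, 3 * y - 7)
  expect_equal(shifted$t_stat, base$t_stat, tolerance = 1e-12)
  expect_equal(shifted$p, base$p, tolerance = 1e-12)
})

test_that("summary-statistic t reproduces the printed star for olive 14:0", {
  # means/SEMs as printed: 1.84 +/- 0.19 (n 9) vs 1.29 +/- 0.12 (n 8)
  res <- t_from_summary(1.84, 0.19, 9, 1.29, 0.12, 8)
  expect_lt(res$p, 0.05)
  expect_equal(sig_stars(res$p), "*")
  expect_lt(res$t_stat, 0)
})

test_that("summary t is zero for equal means and scales inversely with SEM", {
  expect_equal(t_from_summary(5, 0.3, 9, 5, 0.4, 8)$t_stat, 0)
  expect_equal(t_from_summary(5, 0.3, 9, 5, 0.4, 8)$p, 1)
  t1 <- t_from_summary(1, 0.1, 9, 2, 0.1, 8)$t_stat
  t2 <- t_from_summary(1, 0.2, 9, 2, 0.2, 8)$t_stat
  expect_equal(abs(t1) / 2, abs(t2), tolerance = 1e-12)
  # student variant reconstructs per-group SDs and agrees with raw data
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8, 10)
  raw <- t_test_two_sample(y, x, "student_pooled") # signed group2 - group1
  summ <- t_from_summary(
    mean(x), stats::sd(x) / 2, 4, mean(y), stats::sd(y) / sqrt(5), 5,
    t_variant = "student_pooled"
  )
  expect_equal(abs(summ$t_stat), abs(raw$t_stat), tolerance = 1e-10)
  expect_equal(summ$p, raw$p, tolerance = 1e-10)
})

test_that("percent change reproduces the reported aging magnitudes", {
  expect_equal(round(percent_change(1.84, 1.29)), -30)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(round(percent_change(0.05, 0.19)), 280)
  expect_true(is.na(percent_change(0, 1)))
})

# Classic BH step-up as an exhaustive threshold scan, independent of
# p.adjust: reject the k smallest p-values where k is the largest i with
# p_(i) <= i * Q / m.
bh_oracle_reject <- function(p, Q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * Q / m)
  reject <- logical(m)
  if (length(ok)) reject[ord[seq_len(max(ok))]] <- TRUE
  reject
}

test_that("BH adjustment equals the exhaustive step-up oracle", {
  expect_equal(bh_adjust(0.03)$q, 0.03)
  expect_false(any(bh_adjust(rep(1, 5))$discovery))
  set.seed(47)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    res <- bh_adjust(p, Q = 0.10)
    expect_equal(res$discovery, bh_oracle_reject(p, 0.10))
    expect_true(all(res$q >= res$p))
    # q monotone nondecreasing in p-rank
    expect_true(all(diff(res$q[order(res$p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "must lie")
})

test_that("exact Spearman permutation p matches an independent implementation", {
  set.seed(53)
  for (n in c(5, 6, 7)) {
    for (rep in 1:5) {
      x <- sample(seq_len(n) * 10) + stats::runif(n, 0, 0.5)
      age <- sample(40:80, n)
      got <- spearman_age(x, age, method = "exact")
      ct <- suppressWarnings(
        stats::cor.test(x, age, method = "spearman", exact = TRUE)
      )
      expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(got$p, ct$p.value, tolerance = 1e-12)
      expect_identical(got$method, "exact")
    }
  }
})

test_that("Spearman behaves under monotone transforms, sign flips and ties", {
  ages <- c(41, 47, 55, 63, 71, 76)
  x <- c(2, 3, 5, 8, 9, 12)
  expect_equal(spearman_age(x, ages)$rho, 1)
  expect_equal(spearman_age(-x, ages)$rho, -1)
  # strictly monotone transform leaves rho and p unchanged
  a <- spearman_age(x + stats::rnorm(6, sd = 2), ages)
  set.seed(59)
  y <- stats::rnorm(6)
  expect_equal(spearman_age(exp(y), ages)$rho, spearman_age(y, ages)$rho)
  # ties fall back to the t-approximation
  tied <- spearman_age(c(1, 1, 2, 2, 3, 3), ages)
  expect_identical(tied$method, "approx")
  const <- spearman_age(rep(1, 6), ages)
  expect_true(is.na(const$rho))
  expect_error(spearman_age(1:2, 1:2), "at least 3")
})

test_that("age-group split reproduces the 9/8 reference cohort structure", {
  coh <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:17), region = "olive",
    age = table1_ages()
  )
  grp <- split_age_groups(coh)
  expect_equal(nrow(grp$middle_aged), 9)
  expect_equal(nrow(grp$elderly), 8)
  # boundary convention: exactly 60 goes to the elderly group
  at60 <- suppressWarnings(split_age_groups(
    tibble::tibble(subject_id = "x", region = "olive", age = 60)
  ))
  expect_equal(nrow(at60$elderly), 1)
  expect_warning(
    split_age_groups(
      tibble::tibble(subject_id = "x", region = "olive", age = 50)
    ),
    "empty age group"
  )
})

test_that("an extreme group shift is discovered at Q = 0.10", {
  coh <- simulate_cohort(sim_config(
    seed = 61, regions = "frontal", n_subjects = 17, ages = table1_ages()
  ))
  # shift one fatty acid in the elderly by ~5 pooled SDs (pre-closure)
  sd20 <- stats::sd(coh[["20:0"]])
  coh[["20:0"]] <- coh[["20:0"]] + ifelse(coh$age >= 60, 5 * sd20, 0)
  coh[panel_names] <- 100 * coh[panel_names] / rowSums(coh[panel_names])
  res <- run_group_comparison(coh)
  hit <- res[res$variable == "20:0", ]
  expect_true(hit$discovery)
  expect_equal(hit$sig_flags, "***")
  expect_true(all(res$q_adj >= res$p_raw, na.rm = TRUE))
  expect_gt(hit$pct_change, 0)
})

test_that("star coding matches the 0.05 / 0.01 / 0.001 legend", {
  expect_equal(
    sig_stars(c(0.2, 0.049, 0.009, 0.0009, NA)),
    c("", "*", "**", "***", "")
  )
})

test_that("regions with a missing group are skipped with a warning", {
  coh <- simulate_cohort(sim_config(
    seed = 67, regions = "olive", n_subjects = 6,
    ages = c(45, 50, 55, 52, 48, 58)
  ))
  expect_warning(res <- run_group_comparison(coh), "fewer than 2")
  expect_equal(nrow(res), 0)
})

test_that("cross-region matrix is symmetric, unit-diagonal, rho = 1 on copies", {
  coh <- toy_cohort(n = 8, regions = c("olive", "vermis"))
  idxv <- cohort_indexes(coh)
  # make vermis PUFAn6 a strictly monotone copy of olive's
  olive_vals <- idxv$PUFAn6[idxv$region == "olive"]
  rankmap <- rank(olive_vals)
  vermis_rows <- which(coh$region == "vermis")
  # replace vermis profiles with scaled olive profiles (monotone in PUFAn6)
  coh[vermis_rows, panel_names] <- coh[coh$region == "olive", panel_names]
  cm <- correlation_matrix(coh, "PUFAn6")
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 2))
  expect_equal(cm$rho["olive", "vermis"], 1)
  expect_equal(cm$n["olive", "vermis"], 8L)
})

test_that("pairs with too few shared subjects are undefined", {
  coh <- toy_cohort(n = 8, regions = c("olive", "vermis"))
  drop <- coh$region == "vermis" & coh$subject_id %in% sprintf("S%03d", 1:6)
  coh <- coh[!drop, ]
  cm <- correlation_matrix(coh, "ACL")
  expect_true(is.na(cm$rho["olive", "vermis"]))
  expect_equal(cm$n["olive", "vermis"], 2L)
})

test_that("age-continuum correlation recovers an injected trend", {
  coh <- simulate_cohort(sim_config(
    seed = 71, regions = "olive", n_subjects = 100,
    effects = age_effect("20:0", 0.02)
  ))
  res <- run_age_correlation(coh)
  hit <- res[res$variable == "20:0", ]
  expect_gt(hit$rho, 0)
  expect_lt(hit$p_raw, 0.05)
  expect_true(all(res$q_adj >= res$p_raw, na.rm = TRUE))
})
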