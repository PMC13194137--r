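test_that("shapiro gate distinguishes normal from exponential samples", {
  set.seed(101)
  p_norm <- replicate(100, shapiro_normality(rnorm(100))$p)
  expect_gte(mean(p_norm > 0.05), 0.90)
  set.seed(102)
  p_exp <- replicate(100, shapiro_normality(rexp(100))$p)
  expect_gte(mean(p_exp < 0.05), 0.90)
  expect_error(shapiro_normality(c(1, 2)),
               class = "treedraw_insufficient_data_error")
  expect_error(shapiro_normality(rep(3, 10)),
               class = "treedraw_degenerate_error")
})

test_that("summary t-test agrees with stats::t.test on raw data", {
  set.seed(7)
  x <- rnorm(40, 1); y <- rnorm(55)
  ours <- t_test_raw(x, y, variant = "pooled")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)

  ours_w <- t_test_raw(x, y, variant = "welch")
  ref_w <- t.test(x, y)
  expect_equal(ours_w$statistic, unname(ref_w$statistic), tolerance = 1e-12)
  expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-12)
})

test_that("raw and summary t routes are identical to machine precision", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2))
    y <- rnorm(sample(5:40, 1))
    a <- t_test_raw(x, y)
    b <- t_test_summary(mean(x), sd(x), length(x),
                        mean(y), sd(y), length(y))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
  same <- t_test_summary(5, 1, 20, 5, 1, 20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(t_test_summary(1, 0, 10, 2, 0, 10),
               class = "treedraw_degenerate_error")
  expect_error(t_test_raw(1, rnorm(5)),
               class = "treedraw_insufficient_data_error")
})

test_that("two-sided tests flip sign but keep p under group swap", {
  a <- t_test_summary(10, 2, 30, 8, 3, 25)
  b <- t_test_summary(8, 3, 25, 10, 2, 30)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("Mann-Whitney matches exhaustive permutation enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  set.seed(9)
  for (i in 1:6) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:7, 1))
    r <- mann_whitney(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p, mw_enum_p(x, y), tolerance = 1e-12)
  }
  xy <- rnorm(6)
  expect_equal(mann_whitney(xy, xy)$p, 1, tolerance = 0.05)
  big <- rnorm(30)
  expect_equal(mann_whitney(big, rnorm(25))$method,
               "normal-approximation")
})

test_that("chi-square matches closed forms and the published demography", {
  sep <- chi_square(matrix(c(10, 0, 0, 10), 2))
  expect_equal(sep$chisq, 20, tolerance = 1e-12)
  expect_equal(sep$df, 1)
  expect_lt(sep$p, 0.001)

  prop <- chi_square(matrix(c(10, 20, 30, 60), 2))
  expect_equal(prop$chisq, 0, tolerance = 1e-12)

  # gender-matched groups: male/female counts by group
  sex <- chi_square(matrix(c(38, 44, 20, 23, 29, 30), nrow = 2))
  expect_gt(sex$p, 0.05)

  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)),
               class = "treedraw_degenerate_error")
})

test_that("Spearman handles monotone extremes and matches enumeration", {
  x <- c(1, 3, 5, 7, 11)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -exp(x / 10))$rho, -1)
  set.seed(10)
  for (i in 1:4) {
    a <- rnorm(6); b <- rnorm(6)
    r <- spearman(a, b)
    expect_equal(r$p, sp_enum_p(a, b), tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), rnorm(5)),
               class = "treedraw_degenerate_error")
  expect_error(spearman(rnorm(2), rnorm(2)),
               class = "treedraw_insufficient_data_error")
})

test_that("Cohen's d covers unit and degenerate cases", {
  expect_equal(cohens_d(3, 1.2, 30, 3, 1.4, 40), 0)
  expect_equal(cohens_d(1, 1, 50, 0, 1, 50), 1, tolerance = 1e-12)
  expect_error(cohens_d(1, 0, 10, 2, 0, 12),
               class = "treedraw_degenerate_error")
  # severity-score contrast: very large effect
  expect_gt(abs(cohens_d(39.63, 3.31, 43, 4.80, 2.83, 59)), 0.8)
})

test_that("noncentral-t sample size matches Monte-Carlo power", {
  n80 <- required_sample_size(0.8, 0.05, 0.80)
  expect_equal(n80, 26)
  expect_gte(mc_power(26, 0.8), 0.80 - 0.02)
  expect_lt(mc_power(25, 0.8), 0.80)
  # power at the returned n cross-validates within 0.02
  pw <- 1 - pt(qt(0.975, 2 * 26 - 2), 2 * 26 - 2,
               ncp = 0.8 * sqrt(26 / 2)) +
        pt(-qt(0.975, 2 * 26 - 2), 2 * 26 - 2, ncp = 0.8 * sqrt(26 / 2))
  expect_lt(abs(pw - mc_power(26, 0.8)), 0.02)
  # monotone in effect size
  expect_gt(required_sample_size(0.5), required_sample_size(0.8))
  # one-sided needs fewer participants
  expect_lt(required_sample_size(0.5, two_sided = FALSE),
            required_sample_size(0.5))
})

test_that("star annotation follows the footnote thresholds exactly", {
  expect_identical(p_stars(c(0.05, 0.011, 0.01, 0.0099, 0.001, 0.0009)),
                   c("", "", "", "**", "**", "***"))
})

test_that("compare_groups gates on normality and tracks ground truth", {
  cs <- cohort_spec(groups = list(
    low = list(n = 40, area_mean = 55, area_sd = 6, ratio_mean = 3,
               ratio_sd = 0.3, hdrs_mean = 30, hdrs_sd = 6,
               hama_mean = NA, hama_sd = NA, age_range = c(18, 60)),
    high = list(n = 40, area_mean = 110, area_sd = 9, ratio_mean = 4.5,
                ratio_sd = 0.4, hdrs_mean = 5, hdrs_sd = 2,
                hama_mean = NA, hama_sd = NA, age_range = c(18, 60))),
    rho = -0.3, seed = 41)
  g <- generate_cohort(cs)
  roster <- cbind(g$roster, g$truth[, -1])
  cmp <- compare_groups(roster, c("total_area_cm2", "crown_area_cm2"),
                        "low", "high")
  expect_true(all(cmp$mean_1 < cmp$mean_2))  # low group draws smaller trees
  expect_true(all(cmp$p < 0.001))
  expect_true(all(cmp$stars == "***"))
  # pooled-t rows carry the direction in the statistic sign
  tt <- cmp[cmp$test == "pooled-t", ]
  if (nrow(tt)) expect_true(all(tt$statistic < 0))

  # identical groups: no signal
  roster2 <- roster
  roster2$group <- rep(c("x", "y"), length.out = nrow(roster2))
  set.seed(5)
  roster2$noise <- rnorm(nrow(roster2))
  cmp2 <- compare_groups(roster2, "noise", "x", "y")
  expect_gt(cmp2$p, 0.05)

  # constant group routes to the rank test with a note
  roster2$flat <- ifelse(roster2$group == "x", 1,
                         rnorm(nrow(roster2)))
  cmp3 <- compare_groups(roster2, "flat", "x", "y")
  expect_equal(cmp3$test, "mann-whitney")
  expect_equal(cmp3$note, "degenerate-normality-gate")

  expect_error(compare_groups(roster, "nope", "low", "high"),
               class = "treedraw_schema_error")
})

test_that("metric-scale correlations recover the generating rank structure", {
  # homogeneous marginals: the copula is the only source of dependence
  gspec <- list(n = 90, area_mean = 60, area_sd = 8, ratio_mean = 3,
                ratio_sd = 0.3, hdrs_mean = 24, hdrs_sd = 7,
                hama_mean = NA, hama_sd = NA, age_range = c(18, 60))
  cs <- cohort_spec(groups = list(a = gspec, b = gspec),
                    rho = -0.3, seed = 51)
  g <- generate_cohort(cs)
  roster <- cbind(g$roster, g$truth[, -1])
  res <- correlate_with_scale(roster, "total_area_cm2", "hdrs")
  expect_true(res$rho > -0.45 && res$rho < -0.15)
  expect_equal(res$n, 180)

  # shuffled pairing destroys the correlation
  set.seed(6)
  roster$shuffled <- sample(roster$hdrs)
  res0 <- correlate_with_scale(roster, "total_area_cm2", "shuffled")
  expect_lt(abs(res0$rho), 0.2)

  roster$const <- 5
  expect_error(correlate_with_scale(roster, "total_area_cm2", "const"),
               class = "treedraw_degenerate_error")
})

test_that("demographics table reproduces frequency (percent) arithmetic", {
  roster <- data.frame(
    id = sprintf("P%02d", 1:10),
    group = rep(c("case", "control"), each = 5),
    sex = c("male", "male", "female", "female", "female",
            "male", "female", "male", "female", "female"),
    age = c(14:18, 40:44),
    hdrs = c(25, 24, 19, 30, 22, NA, NA, NA, NA, NA))
  d <- demographics_table(roster)
  male_case <- d$counts[d$counts$variable == "sex" &
                          d$counts$level == "male" &
                          d$counts$group == "case", ]
  expect_equal(male_case$n, 2)
  expect_equal(male_case$pct, 40.0)
  expect_equal(male_case$formatted, "2 (40.0%)")
  expect_equal(d$total_n, 10)
  band <- d$counts[d$counts$variable == "hdrs_band" &
                     d$counts$group == "case", ]
  expect_equal(sum(band$n), 5)
  expect_gt(d$sex_chi_square$p, 0.05)
})
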