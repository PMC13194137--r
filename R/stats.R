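# The statistical comparison battery: normality gate, two-sample tests
# (from raw data or from printed summary statistics), chi-square, Spearman
# correlation, Cohen's d, and noncentral-t power analysis.
#
# t_test_summary is the workhorse for checking published tables: group
# means, SDs and ns as printed are enough to recompute a pooled (or Welch)
# t statistic without the raw data.

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, 3 <= n <= 5000 after NA removal.
#' @return list with `W` and `p`.
#' @export
shapiro_normality <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3)
    stop_treedraw("Shapiro-Wilk needs at least 3 observations",
                  "treedraw_insufficient_data_error")
  if (n > 5000)
    stop_treedraw("Shapiro-Wilk limited to n <= 5000",
                  "treedraw_insufficient_data_error")
  if (diff(range(values)) == 0)
    stop_treedraw("constant sample: normality test undefined",
                  "treedraw_degenerate_error")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the independent-samples t statistic from per-group means,
#' standard deviations and sizes — the form needed to audit published
#' tables. The pooled variant uses
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)` with `df = n1+n2-2`;
#' the Welch variant uses unpooled variances with Welch-Satterthwaite df.
#' The p-value is two-sided.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @param variant `"pooled"` (Student) or `"welch"`.
#' @param label optional variable name carried into the result.
#' @return an object of class `group_comparison`: a one-row data frame with
#'   group summaries, `test`, `statistic`, `df`, `p`, `cohens_d`, `stars`.
#' @export
t_test_summary <- function(m1, sd1, n1, m2, sd2, n2,
                           variant = c("pooled", "welch"),
                           label = "") {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0)
    stop_treedraw("both groups have zero variance",
                  "treedraw_degenerate_error")
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  d <- cohens_d(m1, sd1, n1, m2, sd2, n2)
  group_comparison(variable = label, m1 = m1, sd1 = sd1, n1 = n1,
                   m2 = m2, sd2 = sd2, n2 = n2,
                   test = paste0(variant, "-t"), statistic = t, df = df,
                   p = p, cohens_d = d)
}

group_comparison <- function(variable, m1, sd1, n1, m2, sd2, n2,
                             test, statistic, df = NA_real_, p,
                             cohens_d = NA_real_) {
  stopifnot(p >= 0, p <= 1)
  out <- data.frame(variable = variable,
                    mean_1 = m1, sd_1 = sd1, n_1 = n1,
                    mean_2 = m2, sd_2 = sd2, n_2 = n2,
                    test = test, statistic = statistic, df = df, p = p,
                    cohens_d = cohens_d,
                    stars = p_stars(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Significance stars per the table footnote convention
#'
#' `**` for p < 0.01, `***` for p < 0.001, empty otherwise.
#'
#' @param p numeric p-value(s) in \[0, 1\].
#' @return character vector of star annotations.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ""))
}

#' Two-sample t-test from raw samples
#'
#' Identical, by construction, to [t_test_summary()] applied to the
#' samples' own means, SDs and sizes.
#'
#' @param x,y numeric samples, each of size >= 2 after NA removal.
#' @inheritParams t_test_summary
#' @return a `group_comparison` row.
#' @export
t_test_raw <- function(x, y, variant = c("pooled", "welch"), label = "") {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_treedraw("each sample needs at least 2 observations",
                  "treedraw_insufficient_data_error")
  t_test_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                 variant = variant, label = label)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. Uses the exact U distribution when both groups
#' have at most 20 observations and there are no ties; otherwise the normal
#' approximation with the tie correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` (number of (x, y) pairs with x > y), `p`, and
#'   `method` (`"exact"` or `"normal-approximation"`).
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1)
    stop_treedraw("both samples must be non-empty",
                  "treedraw_insufficient_data_error")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 20 && length(y) <= 20
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal-approximation")
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; `df = (r-1)(k-1)`.
#'
#' @param tab matrix of non-negative counts, all row and column sums > 0.
#' @return list with `chisq`, `df`, `p`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0))
    stop_treedraw("counts must be non-negative", "treedraw_degenerate_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_treedraw("zero marginal in contingency table",
                  "treedraw_degenerate_error")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Spearman rank correlation
#'
#' Midrank ties. The two-sided p-value uses the exact permutation
#' distribution for n < 10 without ties and the t approximation otherwise.
#'
#' @param x,y paired numeric vectors; pairs with any NA are dropped;
#'   n >= 3 required.
#' @param pair optional character pair of variable names for the result.
#' @return an object of class `correlation_result`: list with `pair`,
#'   `rho`, `p`, `n`.
#' @export
spearman <- function(x, y, pair = c("x", "y")) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    stop_treedraw("Spearman needs at least 3 complete pairs",
                  "treedraw_insufficient_data_error")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop_treedraw("constant input: correlation undefined",
                  "treedraw_degenerate_error")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = n < 10 && !ties))
  structure(list(pair = pair, rho = unname(ct$estimate), p = ct$p.value,
                 n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s ~ %s: rho = %.3f, p = %.4g, n = %d\n",
              x$pair[1], x$pair[2], x$rho, x$p, x$n))
  invisible(x)
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference `(m1 - m2) / sp` with the pooled SD.
#'
#' @inheritParams t_test_summary
#' @return numeric effect size.
#' @export
cohens_d <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0)
    stop_treedraw("pooled SD is zero: effect size undefined",
                  "treedraw_degenerate_error")
  (m1 - m2) / sp
}

#' Minimum per-group sample size for a two-sample t-test
#'
#' Iterates n upward, computing the power of the two-sample pooled t-test
#' at `df = 2n - 2` and noncentrality `d * sqrt(n / 2)` with the noncentral
#' t distribution, and returns the smallest n attaining the requested
#' power.
#'
#' @param d standardized effect size (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param two_sided two-sided test (default) or one-sided.
#' @return integer, participants per group.
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.80,
                                 two_sided = TRUE) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:1e6) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    if (two_sided) {
      tc <- qt(1 - alpha / 2, df)
      pw <- 1 - pt(tc, df, ncp = ncp) + pt(-tc, df, ncp = ncp)
    } else {
      tc <- qt(1 - alpha, df)
      pw <- 1 - pt(tc, df, ncp = ncp)
    }
    if (pw >= power) return(n)
  }
  stop_treedraw("requested power not reached within iteration limit",
                "treedraw_iteration_error")
}

#' Compare two groups across roster variables
#'
#' For each variable, both groups are gated through Shapiro-Wilk at
#' `alpha_normal`; if both pass, a pooled two-sample t-test is used,
#' otherwise Mann-Whitney. A group that is constant (degenerate for
#' Shapiro-Wilk) routes the variable to the rank test and flags it.
#' No multiple-testing correction is applied, matching the reporting
#' convention of the tables this mirrors.
#'
#' @param roster data frame with a `group` column and the variables.
#' @param variables character vector of numeric column names.
#' @param group_a,group_b group labels to compare (a vs b; positive
#'   statistics mean a > b).
#' @param alpha_normal normality-gate level (default 0.05).
#' @return data frame, one `group_comparison` row per variable, with an
#'   extra `note` column.
#' @export
compare_groups <- function(roster, variables, group_a, group_b,
                           alpha_normal = 0.05) {
  stopifnot(is.data.frame(roster), "group" %in% names(roster))
  missing_vars <- setdiff(variables, names(roster))
  if (length(missing_vars))
    stop_treedraw(paste("variables absent from roster:",
                        paste(missing_vars, collapse = ", ")),
                  "treedraw_schema_error")
  for (g in c(group_a, group_b))
    if (!g %in% roster$group)
      stop_treedraw(sprintf("group '%s' not present in roster", g),
                    "treedraw_schema_error")
  out <- lapply(variables, function(v) {
    x <- roster[[v]][roster$group == group_a]
    y <- roster[[v]][roster$group == group_b]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    norm <- vapply(list(x, y), function(s) {
      tryCatch(shapiro_normality(s)$p >= alpha_normal,
               treedraw_error = function(e) NA)
    }, logical(1))
    note <- ""
    if (anyNA(norm)) note <- "degenerate-normality-gate"
    if (!anyNA(norm) && all(norm)) {
      res <- t_test_raw(x, y, variant = "pooled", label = v)
    } else {
      mw <- mann_whitney(x, y)
      d <- tryCatch(cohens_d(mean(x), sd(x), length(x),
                             mean(y), sd(y), length(y)),
                    treedraw_error = function(e) NA_real_)
      res <- group_comparison(variable = v,
                              m1 = mean(x), sd1 = sd(x), n1 = length(x),
                              m2 = mean(y), sd2 = sd(y), n2 = length(y),
                              test = "mann-whitney", statistic = mw$U,
                              df = NA_real_, p = mw$p, cohens_d = d)
    }
    res$note <- note
    res
  })
  out <- do.call(rbind, out)
  attr(out, "groups") <- c(group_a, group_b)
  out
}

#' Correlate metric variables with a severity scale
#'
#' Spearman correlation of each metric against the scale, with listwise
#' deletion per pair.
#'
#' @param roster data frame holding the columns.
#' @param metric_vars character vector of metric column names.
#' @param scale_var scale column name (e.g. `"hdrs"`).
#' @return data frame with columns `variable`, `rho`, `p`, `n`, `stars`.
#' @export
correlate_with_scale <- function(roster, metric_vars, scale_var) {
  stopifnot(is.data.frame(roster))
  missing_vars <- setdiff(c(metric_vars, scale_var), names(roster))
  if (length(missing_vars))
    stop_treedraw(paste("columns absent from roster:",
                        paste(missing_vars, collapse = ", ")),
                  "treedraw_schema_error")
  rows <- lapply(metric_vars, function(v) {
    keep <- complete.cases(roster[[v]], roster[[scale_var]])
    if (sum(keep) < 3)
      stop_treedraw(sprintf("fewer than 3 complete pairs for '%s'", v),
                    "treedraw_insufficient_data_error")
    r <- spearman(roster[[v]][keep], roster[[scale_var]][keep],
                  pair = c(v, scale_var))
    data.frame(variable = v, rho = r$rho, p = r$p, n = r$n,
               stars = p_stars(r$p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Demographic summary table
#'
#' Frequency (percent) breakdowns per group for the categorical roster
#' columns and mean +/- SD for age, in the layout of a clinical Table 1.
#' Percentages use half-up rounding to one decimal.
#'
#' @param roster data frame with `group`, `sex`, `age`, and optionally
#'   `education` and `hdrs` columns.
#' @param hdrs_breaks cut points for the HDRS banding rows (default bands
#'   19-22 and >= 23).
#' @return list with `counts` (long data frame: variable, level, group, n,
#'   pct, formatted), `age` (per-group mean/sd), `total_n`, and
#'   `sex_chi_square` (the gender-matching check).
#' @export
demographics_table <- function(roster, hdrs_breaks = c(19, 23)) {
  stopifnot(is.data.frame(roster), all(c("group", "sex") %in% names(roster)))
  groups <- unique(roster$group)
  cat_block <- function(variable, values) {
    lv <- unique(values[!is.na(values)])
    do.call(rbind, lapply(groups, function(g) {
      in_g <- roster$group == g & !is.na(values)
      ng <- sum(in_g)
      do.call(rbind, lapply(lv, function(l) {
        n <- sum(values[in_g] == l)
        pct <- if (ng == 0) NA_real_ else round_half_up(100 * n / ng, 1)
        data.frame(variable = variable, level = as.character(l), group = g,
                   n = n, pct = pct,
                   formatted = sprintf("%d (%.1f%%)", n, pct),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  counts <- cat_block("sex", roster$sex)
  if ("education" %in% names(roster))
    counts <- rbind(counts, cat_block("education", roster$education))
  if ("hdrs" %in% names(roster)) {
    band <- ifelse(is.na(roster$hdrs), NA,
                   ifelse(roster$hdrs >= hdrs_breaks[2],
                          sprintf(">= %d", hdrs_breaks[2]),
                          sprintf("%d-%d", hdrs_breaks[1],
                                  hdrs_breaks[2] - 1)))
    counts <- rbind(counts, cat_block("hdrs_band", band))
  }
  age <- NULL
  if ("age" %in% names(roster)) {
    age <- do.call(rbind, lapply(groups, function(g) {
      a <- roster$age[roster$group == g]
      data.frame(group = g, mean = mean(a, na.rm = TRUE),
                 sd = sd(a, na.rm = TRUE), stringsAsFactors = FALSE)
    }))
  }
  sex_tab <- table(roster$sex, roster$group)
  sex_chi <- if (all(dim(sex_tab) >= 2)) chi_square(sex_tab) else NULL
  list(counts = counts, age = age, total_n = nrow(roster),
       sex_chi_square = sex_chi)
}
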