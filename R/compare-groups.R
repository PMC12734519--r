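TABLE1_CONTINUOUS <- c(
  age_years = "Age (years)",
  duration_years = "Duration of diabetes (years)",
  onset_age_years = "Age at onset of diabetes (years)",
  hba1c_current_pct = "Current HbA1c level (%)",
  sbp_mmhg = "Systolic BP (mm Hg)",
  dbp_mmhg = "Diastolic BP (mm Hg)",
  fasting_glucose_mmol_l = "Current blood glucose level (mmol/L)",
  total_chol_mmol_l = "Total cholesterol (mmol/L)",
  ldl_mmol_l = "LDL (mmol/L)",
  tg_mmol_l = "Triglycerides (mmol/L)")

fmt_num <- function(x, digits = 1) formatC(x, format = "f", digits = digits)

summary_median <- function(v) {
  sprintf("%s [%s-%s]", fmt_num(stats::median(v)), fmt_num(min(v)),
          fmt_num(max(v)))
}
summary_mean <- function(v) {
  sprintf("%s (%s)", fmt_num(mean(v), 2), fmt_num(sd(v), 2))
}
summary_counts <- function(v, levels) {
  n <- length(v)
  paste(vapply(levels, function(l) {
    k <- sum(v == l)
    sprintf("%d %s (%d%%)", k, l, as.integer(round_half_up(100 * k / n)))
  }, character(1)), collapse = " / ")
}

#' Full between-group comparison of a cohort
#'
#' Reproduces the study's analysis battery on an arbitrary cohort.  For each
#' continuous variable, both group samples are routed through
#' [normality_route()]; if either deviates from normality the groups are
#' compared with [mann_whitney_shift()] and summarised as median \[min-max\],
#' otherwise with [pooled_t_test()] and mean (SD) summaries.  Categorical
#' characteristics (sex, long-term control, exam regularity) are compared by
#' chi-square.  Each of the four dichotomized risk factors is cross-tabulated
#' with [dichotomize()] and tested with [chi_square_corrected()] and
#' [odds_ratio()].
#'
#' @param cohort a validated cohort containing both groups.
#' @param conf_level confidence level for odds-ratio and shift intervals.
#' @param alpha significance level for normality routing.
#' @param duration_threshold explicit duration split; `NULL` uses the cohort
#'   median.
#' @param tie_policy tie handling for the duration split (see
#'   [dichotomize()]).
#' @param correct use the Yates continuity correction for chi-square tests.
#' @return list of class `pdr_comparison` with elements `table1` (one row
#'   per characteristic: summaries, test used, statistic, p-value) and
#'   `table2` (one row per risk factor: 2x2 counts, chi-square, odds ratio
#'   with CI), both tibbles in the study's reporting order.
#' @examples
#' comp <- compare_groups(fixture_cohort())
#' comp$table2[, c("factor", "or", "ci_low", "ci_high")]
#' @export
compare_groups <- function(cohort, conf_level = 0.95, alpha = 0.05,
                           duration_threshold = NULL,
                           tie_policy = c("error", "lower", "upper"),
                           correct = TRUE) {
  tie_policy <- match.arg(tie_policy)
  validate_cohort(cohort)
  for (g in COHORT_GROUPS) {
    if (!any(cohort$group == g)) {
      abort_input("cohort has no records in group ", g)
    }
  }
  pdr <- cohort[cohort$group == "PDR", ]
  npdr <- cohort[cohort$group == "NPDR", ]

  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- tibble::tibble(...)

  route_var <- function(x, y) {
    if (length(x) < 4L || length(y) < 4L) return("non_normal")
    if (normality_route(x, alpha)$route == "non_normal" ||
        normality_route(y, alpha)$route == "non_normal") "non_normal"
    else "normal"
  }

  cont_row <- function(var, label) {
    x <- pdr[[var]]; y <- npdr[[var]]
    if (route_var(x, y) == "non_normal") {
      res <- mann_whitney_shift(x, y, conf_level = conf_level)
      add_row(variable = var, label = label, test = "mann_whitney",
              pdr_summary = summary_median(x), npdr_summary = summary_median(y),
              statistic = res$z, p_value = res$p_value)
    } else {
      res <- pooled_t_test(x, y)
      add_row(variable = var, label = label, test = "t_test",
              pdr_summary = summary_mean(x), npdr_summary = summary_mean(y),
              statistic = res$statistic, p_value = res$p_value)
    }
  }

  cat_row <- function(var, label, levels, risk_value) {
    tab <- contingency_2x2(a = sum(pdr[[var]] == risk_value),
                           b = sum(npdr[[var]] == risk_value),
                           c = sum(pdr[[var]] != risk_value),
                           d = sum(npdr[[var]] != risk_value))
    res <- chi_square_corrected(tab, correct = correct)
    add_row(variable = var, label = label, test = "chi_square",
            pdr_summary = summary_counts(pdr[[var]], levels),
            npdr_summary = summary_counts(npdr[[var]], levels),
            statistic = res$statistic, p_value = res$p_value)
  }

  # reporting order follows the study's descriptive table
  cont_row("age_years", TABLE1_CONTINUOUS[["age_years"]])
  cat_row("sex", "Sex", c("female", "male"), "female")
  for (var in setdiff(names(TABLE1_CONTINUOUS), "age_years")) {
    cont_row(var, TABLE1_CONTINUOUS[[var]])
  }
  cat_row("longterm_control", "Long-term blood glucose control",
          c("good", "poor"), "poor")
  cat_row("exam_regularity", "Regularity of ophthalmological examinations",
          c("regular", "irregular"), "irregular")
  table1 <- do.call(rbind, rows)

  factors <- default_risk_factors(duration_threshold)
  frow <- function(f) {
    tab <- dichotomize(cohort, f, tie_policy = tie_policy)
    orr <- odds_ratio(tab, conf_level = conf_level)
    cs <- chi_square_corrected(tab, correct = correct)
    tibble::tibble(
      factor = f$name, risk_level = f$risk_level,
      reference_level = f$reference_level,
      threshold = attr(tab, "threshold"),
      pdr_risk = tab$a, npdr_risk = tab$b,
      pdr_ref = tab$c, npdr_ref = tab$d,
      chisq = cs$statistic, chisq_p = cs$p_value,
      or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
      or_p = orr$p_value, continuity_adjusted = orr$continuity_adjusted)
  }
  table2 <- do.call(rbind, lapply(factors, frow))

  structure(list(table1 = table1, table2 = table2,
                 n_pdr = nrow(pdr), n_npdr = nrow(npdr)),
            class = "pdr_comparison")
}

#' @export
print.pdr_comparison <- function(x, ...) {
  cat(render_comparison(x), sep = "\n")
  invisible(x)
}

#' Render a comparison as aligned text
#'
#' @param comp a `pdr_comparison` from [compare_groups()].
#' @return character vector of report lines.
#' @export
render_comparison <- function(comp) {
  t1 <- comp$table1
  t2 <- comp$table2
  lines <- c(
    sprintf("Group comparison: %d PDR vs %d NPDR patients",
            comp$n_pdr, comp$n_npdr), "",
    "Characteristics",
    sprintf("  %-42s %-22s %-22s %-12s %8s %8s",
            "Variable", "PDR", "NPDR", "Test", "Stat", "p"))
  lines <- c(lines, sprintf("  %-42s %-22s %-22s %-12s %8.3f %8.4g",
                            t1$label, t1$pdr_summary, t1$npdr_summary,
                            t1$test, t1$statistic, t1$p_value))
  lines <- c(lines, "", "Dichotomized risk factors",
             sprintf("  %-18s %11s %11s %8s %8s %22s",
                     "Factor", "PDR a/c", "NPDR b/d", "chi2", "p",
                     "OR (95% CI)"))
  lines <- c(lines, sprintf(
    "  %-18s %11s %11s %8.2f %8.4g %22s",
    t2$factor, paste0(t2$pdr_risk, "/", t2$pdr_ref),
    paste0(t2$npdr_risk, "/", t2$npdr_ref), t2$chisq, t2$chisq_p,
    sprintf("%.2f (%.2f-%.2f)", t2$or, t2$ci_low, t2$ci_high)))
  lines
}
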