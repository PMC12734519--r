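#' Define a dichotomous risk factor
#'
#' @param name short identifier for the factor.
#' @param variable cohort column the factor is computed from.
#' @param risk_level,reference_level display labels for the risk and
#'   reference levels.
#' @param risk_value for categorical variables, the value counted as risk.
#' @param threshold for numeric variables, the split point; `NULL` means
#'   "use the analyzed cohort's own median" (midpoint convention for even n).
#' @param direction `"gt"` (risk = value strictly above threshold) or
#'   `"le"` (risk = value at or below threshold).
#' @return a list of class `risk_factor`.
#' @export
risk_factor <- function(name, variable, risk_level, reference_level,
                        risk_value = NULL, threshold = NULL,
                        direction = c("gt", "le")) {
  direction <- match.arg(direction)
  structure(list(name = name, variable = variable, risk_level = risk_level,
                 reference_level = reference_level, risk_value = risk_value,
                 threshold = threshold, direction = direction),
            class = "risk_factor")
}

#' The study's four built-in risk factors
#'
#' Poor long-term glycaemic control (HbA1c > 7%), irregular ophthalmological
#' examinations, diabetes onset at or before 18 years, and diabetes duration
#' above the cohort median (22.5 years in the study cohort).
#'
#' @param duration_threshold split point for the duration factor; `NULL`
#'   (default) uses the analyzed cohort's own median.
#' @return named list of [risk_factor()] objects in reporting order.
#' @export
default_risk_factors <- function(duration_threshold = NULL) {
  list(
    longterm_control = risk_factor(
      "longterm_control", "longterm_control",
      risk_level = "Poor (HbA1c > 7%)", reference_level = "Good (HbA1c <= 7%)",
      risk_value = "poor"),
    exam_regularity = risk_factor(
      "exam_regularity", "exam_regularity",
      risk_level = "Irregular", reference_level = "Regular",
      risk_value = "irregular"),
    onset_age = risk_factor(
      "onset_age", "onset_age_years",
      risk_level = "<=18 years", reference_level = ">18 years",
      threshold = 18, direction = "le"),
    duration = risk_factor(
      "duration", "duration_years",
      risk_level = paste0(">", duration_threshold %||% "median", " years"),
      reference_level = paste0("<=", duration_threshold %||% "median",
                               " years"),
      threshold = duration_threshold, direction = "gt"))
}

#' Construct a 2x2 exposure-by-outcome contingency table
#'
#' Cell layout: `a` = risk level & PDR, `b` = risk level & NPDR,
#' `c` = reference level & PDR, `d` = reference level & NPDR.
#'
#' @param a,b,c,d non-negative integer counts, not all zero.
#' @return a list of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    abort_input("contingency cells must be non-negative integers")
  }
  if (sum(cells) == 0) abort_input("contingency table must have a positive total")
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(c("risk", "reference"), c("PDR", "NPDR")))
  print(m)
  invisible(x)
}

#' Dichotomize a cohort by one risk factor
#'
#' Assigns every record to the factor's risk or reference level and
#' cross-tabulates against the PDR/NPDR group label.  For numeric factors
#' with an exclusive threshold (`direction = "gt"`), records lying exactly on
#' the threshold have no natural side; by default this is an error listing
#' the patient ids, forcing the caller to pick an explicit tie policy.
#'
#' @param cohort a validated cohort (non-empty).
#' @param factor a [risk_factor()].
#' @param tie_policy what to do with records exactly at an exclusive
#'   threshold: `"error"` (default), `"lower"` (assign to the \eqn{\le}
#'   reference side), or `"upper"` (assign to the risk side).
#' @return a [contingency_2x2()] with attributes `factor` (the definition,
#'   with any cohort-derived threshold filled in) and `threshold`.
#' @examples
#' dichotomize(fixture_cohort(), default_risk_factors()$onset_age)
#' @export
dichotomize <- function(cohort, factor, tie_policy = c("error", "lower", "upper")) {
  tie_policy <- match.arg(tie_policy)
  if (!inherits(factor, "risk_factor")) abort_input("`factor` must be a risk_factor")
  if (is.null(cohort) || nrow(cohort) == 0L) {
    abort_input("cannot dichotomize an empty cohort")
  }
  if (!factor$variable %in% names(cohort)) {
    abort_input("cohort has no column `", factor$variable, "`")
  }
  v <- cohort[[factor$variable]]
  threshold <- NA_real_
  if (!is.null(factor$risk_value)) {
    risk <- v == factor$risk_value
  } else {
    threshold <- factor$threshold %||% stats::median(v)
    if (factor$direction == "gt") {
      at <- which(v == threshold)
      if (length(at) > 0L) {
        if (tie_policy == "error") {
          abort_input("records exactly at the ", factor$name, " threshold (",
                      threshold, "): ",
                      paste(cohort$patient_id[at], collapse = ", "),
                      "; set tie_policy = \"lower\" or \"upper\"")
        }
        risk <- if (tie_policy == "upper") v >= threshold else v > threshold
      } else {
        risk <- v > threshold
      }
    } else {
      risk <- v <= threshold
    }
  }
  is_pdr <- cohort$group == "PDR"
  tab <- contingency_2x2(a = sum(risk & is_pdr), b = sum(risk & !is_pdr),
                         c = sum(!risk & is_pdr), d = sum(!risk & !is_pdr))
  attr(tab, "factor") <- factor
  attr(tab, "threshold") <- threshold
  tab
}
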