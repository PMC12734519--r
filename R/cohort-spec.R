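# Column schema for a patient cohort.  Enum fields are stored as lower-case
# strings except `group`, which uses the clinical labels "PDR"/"NPDR".

COHORT_GROUPS <- c("PDR", "NPDR")

# variables summarised as median [min-max] in the source tables (skewed) vs
# mean +/- SD (treated as symmetric)
SKEWED_VARS <- c("duration_years", "onset_age_years", "ldl_mmol_l",
                 "tg_mmol_l", "age_years")
SYMMETRIC_VARS <- c("hba1c_current_pct", "fasting_glucose_mmol_l",
                    "sbp_mmhg", "dbp_mmhg", "total_chol_mmol_l")

COHORT_COLUMNS <- c("patient_id", "group", "sex", "age_years",
                    "onset_age_years", "duration_years", "hba1c_current_pct",
                    "fasting_glucose_mmol_l", "sbp_mmhg", "dbp_mmhg",
                    "total_chol_mmol_l", "ldl_mmol_l", "tg_mmol_l",
                    "longterm_control", "exam_regularity")

COHORT_NUMERIC_COLUMNS <- c("age_years", "onset_age_years", "duration_years",
                            "hba1c_current_pct", "fasting_glucose_mmol_l",
                            "sbp_mmhg", "dbp_mmhg", "total_chol_mmol_l",
                            "ldl_mmol_l", "tg_mmol_l")

#' Distributional targets for one patient group
#'
#' Bundles the per-group targets a synthetic cohort is generated against:
#' group size, the sex split, median/range targets for skewed variables,
#' mean/SD targets for symmetric variables, and the two categorical risk
#' fractions (poor long-term glycaemic control, irregular eye exams).
#'
#' @param n number of patients in the group.
#' @param sex_female_fraction probability that a patient is female.
#' @param skewed named list; one `c(median, min, max)` triple per variable in
#'   `duration_years`, `onset_age_years`, `ldl_mmol_l`, `tg_mmol_l`,
#'   `age_years`.
#' @param symmetric named list; one `c(mean, sd)` pair per variable in
#'   `hba1c_current_pct`, `fasting_glucose_mmol_l`, `sbp_mmhg`, `dbp_mmhg`,
#'   `total_chol_mmol_l`.
#' @param longterm_poor_fraction fraction with poor long-term control
#'   (HbA1c > 7%).
#' @param exam_irregular_fraction fraction with irregular ophthalmological
#'   examinations.
#' @return a list of class `group_targets`.
#' @export
group_targets <- function(n, sex_female_fraction, skewed, symmetric,
                          longterm_poor_fraction, exam_irregular_fraction) {
  structure(list(n = n,
                 sex_female_fraction = sex_female_fraction,
                 skewed = skewed,
                 symmetric = symmetric,
                 longterm_poor_fraction = longterm_poor_fraction,
                 exam_irregular_fraction = exam_irregular_fraction),
            class = "group_targets")
}

#' Build a cohort specification
#'
#' @param PDR,NPDR [group_targets()] objects for the case (proliferative
#'   retinopathy) and comparator groups.
#' @return a list of class `cohort_spec`; validated with
#'   [validate_cohort_spec()].
#' @seealso [table1_cohort_spec()] for the study defaults.
#' @export
cohort_spec <- function(PDR, NPDR) {
  spec <- structure(list(PDR = PDR, NPDR = NPDR), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Default cohort specification from the study summary tables
#'
#' Encodes the published per-group summaries of the 58-patient Croatian
#' young-onset type 1 diabetes cohort (27 PDR cases, 31 NPDR comparators):
#' median \[min-max\] targets for the skewed variables, mean (SD) targets for
#' the symmetric ones, the sex split, and the two categorical risk fractions.
#' Group sizes can be scaled up for large-sample work while keeping every
#' distributional target fixed.
#'
#' @param n_pdr,n_npdr group sizes; defaults are the study's 27 and 31.
#' @return a `cohort_spec`.
#' @examples
#' spec <- table1_cohort_spec(n_pdr = 1000, n_npdr = 1000)
#' cohort <- generate_cohort(spec, seed = 1)
#' @export
table1_cohort_spec <- function(n_pdr = 27, n_npdr = 31) {
  cohort_spec(
    PDR = group_targets(
      n = n_pdr,
      sex_female_fraction = 12 / 27,
      skewed = list(
        duration_years  = c(median = 31,  min = 15,  max = 40),
        onset_age_years = c(median = 18,  min = 10,  max = 30),
        ldl_mmol_l      = c(median = 2.6, min = 1,   max = 4),
        tg_mmol_l       = c(median = 1.9, min = 0.9, max = 2.7),
        age_years       = c(median = 49,  min = 28,  max = 58)),
      symmetric = list(
        hba1c_current_pct      = c(mean = 7.9,  sd = 1.4),
        fasting_glucose_mmol_l = c(mean = 7.5,  sd = 1.4),
        sbp_mmhg               = c(mean = 139,  sd = 10),
        dbp_mmhg               = c(mean = 86,   sd = 4.7),
        total_chol_mmol_l      = c(mean = 4.34, sd = 1.10)),
      longterm_poor_fraction = 23 / 27,
      exam_irregular_fraction = 22 / 27),
    NPDR = group_targets(
      n = n_npdr,
      sex_female_fraction = 13 / 31,
      skewed = list(
        duration_years  = c(median = 20,  min = 10, max = 27),
        onset_age_years = c(median = 28,  min = 17, max = 30),
        ldl_mmol_l      = c(median = 1.7, min = 1,  max = 3),
        tg_mmol_l       = c(median = 1.5, min = 0,  max = 2),
        age_years       = c(median = 47,  min = 35, max = 55)),
      symmetric = list(
        hba1c_current_pct      = c(mean = 5.9,  sd = 0.7),
        fasting_glucose_mmol_l = c(mean = 6.0,  sd = 0.7),
        sbp_mmhg               = c(mean = 129,  sd = 10),
        dbp_mmhg               = c(mean = 81,   sd = 9.2),
        total_chol_mmol_l      = c(mean = 4.14, sd = 0.81)),
      longterm_poor_fraction = 9 / 31,
      exam_irregular_fraction = 4 / 31))
}

#' Validate a cohort specification
#'
#' Checks group sizes, fractions, and the per-variable targets; the error
#' message names the first offending field (e.g. `PDR$skewed$duration_years`).
#'
#' @param spec a `cohort_spec`.
#' @return the spec, invisibly.
#' @export
validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort_input("`spec` must be a cohort_spec")
  for (g in COHORT_GROUPS) {
    gs <- spec[[g]]
    if (is.null(gs)) abort_input("cohort spec is missing group ", g)
    bad <- function(field, msg) {
      abort_input("invalid cohort spec field ", g, "$", field, ": ", msg)
    }
    n <- gs$n
    if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
        n != floor(n)) {
      bad("n", "must be a single non-negative integer")
    }
    for (f in c("sex_female_fraction", "longterm_poor_fraction",
                "exam_irregular_fraction")) {
      v <- gs[[f]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
        bad(f, "must be a probability in [0, 1]")
      }
    }
    for (var in SKEWED_VARS) {
      tr <- gs$skewed[[var]]
      if (is.null(tr) || length(tr) != 3L || anyNA(tr)) {
        bad(paste0("skewed$", var), "must be c(median, min, max)")
      }
      if (!(tr[["min"]] < tr[["median"]] && tr[["median"]] < tr[["max"]])) {
        bad(paste0("skewed$", var), "requires min < median < max")
      }
    }
    for (var in SYMMETRIC_VARS) {
      tr <- gs$symmetric[[var]]
      if (is.null(tr) || length(tr) != 2L || anyNA(tr)) {
        bad(paste0("symmetric$", var), "must be c(mean, sd)")
      }
      if (tr[["sd"]] <= 0) bad(paste0("symmetric$", var), "requires sd > 0")
    }
  }
  invisible(spec)
}

#' Validate a patient cohort
#'
#' Enforces the record-level invariants of the study population on every row:
#' diabetes duration over five years (inclusion rule), onset at or before age
#' 30 (young-onset definition), internal age consistency
#' `|age - (onset + duration)| <= 2` years, strictly positive clinical
#' measurements (triglycerides may be zero), and valid category labels.
#'
#' @param cohort a data frame with the cohort columns (see [fixture_cohort()]
#'   for the schema).
#' @param context label used in error messages (e.g. a file name).
#' @return the cohort, invisibly; errors identify the row and field at fault.
#' @export
validate_cohort <- function(cohort, context = "cohort") {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0L) {
    abort_input(context, ": missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  fail <- function(rows, field, msg) {
    abort_input(context, ": row ", paste(utils::head(rows, 5L), collapse = ", "),
                if (length(rows) > 5L) " (and others)" else "",
                ", field `", field, "`: ", msg)
  }
  if (nrow(cohort) == 0L) return(invisible(cohort))

  check_enum <- function(field, levels) {
    bad <- which(!(cohort[[field]] %in% levels))
    if (length(bad)) fail(bad, field,
                          paste0("must be one of ",
                                 paste(levels, collapse = "/")))
  }
  check_enum("group", COHORT_GROUPS)
  check_enum("sex", c("female", "male"))
  check_enum("longterm_control", c("good", "poor"))
  check_enum("exam_regularity", c("regular", "irregular"))

  for (field in COHORT_NUMERIC_COLUMNS) {
    v <- cohort[[field]]
    if (!is.numeric(v)) fail(seq_len(nrow(cohort)), field, "must be numeric")
    bad <- which(!is.finite(v))
    if (length(bad)) fail(bad, field, "missing or non-finite value")
  }

  pos_fields <- setdiff(COHORT_NUMERIC_COLUMNS, "tg_mmol_l")
  for (field in pos_fields) {
    bad <- which(cohort[[field]] <= 0)
    if (length(bad)) fail(bad, field, "must be strictly positive")
  }
  bad <- which(cohort$tg_mmol_l < 0)
  if (length(bad)) fail(bad, "tg_mmol_l", "must be non-negative")

  bad <- which(cohort$duration_years <= 5)
  if (length(bad)) fail(bad, "duration_years",
                        "inclusion requires diabetes duration > 5 years")
  bad <- which(cohort$onset_age_years > 30)
  if (length(bad)) fail(bad, "onset_age_years",
                        "young-onset inclusion requires onset age <= 30 years")
  # tolerance covers one ulp of double rounding at the 2-year clip boundary
  bad <- which(abs(cohort$age_years -
                   (cohort$onset_age_years + cohort$duration_years)) >
               2 + 1e-9)
  if (length(bad)) fail(bad, "age_years",
                        "age must equal onset age + duration within 2 years")
  invisible(cohort)
}
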