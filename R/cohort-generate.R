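# Skewed bounded variables are drawn from a Beta distribution rescaled to
# [min, max].  The first shape parameter is fixed at 2 (guaranteeing a
# unimodal density with no mass spike at the endpoints) and the second is
# solved so the distribution median sits exactly on the target median.
beta_shape_for_median <- function(median_rel) {
  stopifnot(median_rel > 0, median_rel < 1)
  # qbeta(0.5, 2, b) decreases monotonically from ~1 (b -> 0) to ~0 (b -> Inf);
  # qbeta warns about reduced accuracy at the extreme bracket endpoints, which
  # only serve to enclose the root
  f <- function(log_b) suppressWarnings(qbeta(0.5, 2, exp(log_b))) - median_rel
  root <- uniroot(f, lower = log(1e-3), upper = log(1e3), tol = 1e-12)
  exp(root$root)
}

draw_skewed <- function(n, target) {
  lo <- target[["min"]]
  hi <- target[["max"]]
  med_rel <- (target[["median"]] - lo) / (hi - lo)
  b <- beta_shape_for_median(med_rel)
  lo + (hi - lo) * rbeta(n, shape1 = 2, shape2 = b)
}

# normal draw truncated below at `lower` (physiologic positivity) by
# resampling; all study means sit many SDs above zero so acceptance is ~1
draw_truncated_normal <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  for (iter in 1:100) {
    bad <- which(x <= lower)
    if (length(bad) == 0L) return(x)
    x[bad] <- rnorm(length(bad), mean, sd)
  }
  x[x <= lower] <- lower + sd * 1e-3
  x
}

generate_group <- function(group, gs) {
  n <- gs$n
  if (n == 0L) {
    return(empty_cohort())
  }
  duration <- draw_skewed(n, gs$skewed$duration_years)
  # keep the default duration split threshold free of exact ties
  duration[duration == 22.5] <- 22.5 + 1e-9
  onset <- draw_skewed(n, gs$skewed$onset_age_years)
  ldl <- draw_skewed(n, gs$skewed$ldl_mmol_l)
  tg <- draw_skewed(n, gs$skewed$tg_mmol_l)

  # age is derived, not sampled: clip into the target range but never more
  # than 2 years from onset + duration, preserving the record invariant
  s <- onset + duration
  age_t <- gs$skewed$age_years
  age <- pmin(pmax(s, age_t[["min"]]), age_t[["max"]])
  age <- pmin(pmax(age, s - 2), s + 2)

  sym <- lapply(gs$symmetric, function(tr) {
    draw_truncated_normal(n, tr[["mean"]], tr[["sd"]])
  })

  sex <- ifelse(runif(n) < gs$sex_female_fraction, "female", "male")
  longterm <- ifelse(runif(n) < gs$longterm_poor_fraction, "poor", "good")
  exam <- ifelse(runif(n) < gs$exam_irregular_fraction, "irregular", "regular")

  tibble::tibble(
    patient_id = sprintf("%s-%06d", tolower(group), seq_len(n)),
    group = group,
    sex = sex,
    age_years = age,
    onset_age_years = onset,
    duration_years = duration,
    hba1c_current_pct = sym$hba1c_current_pct,
    fasting_glucose_mmol_l = sym$fasting_glucose_mmol_l,
    sbp_mmhg = sym$sbp_mmhg,
    dbp_mmhg = sym$dbp_mmhg,
    total_chol_mmol_l = sym$total_chol_mmol_l,
    ldl_mmol_l = ldl,
    tg_mmol_l = tg,
    longterm_control = longterm,
    exam_regularity = exam)
}

empty_cohort <- function() {
  tibble::tibble(
    patient_id = character(), group = character(), sex = character(),
    age_years = numeric(), onset_age_years = numeric(),
    duration_years = numeric(), hba1c_current_pct = numeric(),
    fasting_glucose_mmol_l = numeric(), sbp_mmhg = numeric(),
    dbp_mmhg = numeric(), total_chol_mmol_l = numeric(),
    ldl_mmol_l = numeric(), tg_mmol_l = numeric(),
    longterm_control = character(), exam_regularity = character())
}

#' Generate a synthetic patient cohort
#'
#' Draws a PDR and an NPDR group whose large-sample statistics converge on
#' the targets in `spec`.  Skewed variables (duration, onset age, LDL,
#' triglycerides) come from a Beta distribution rescaled to the target
#' \[min, max\] with shapes solved so the distribution median equals the
#' target median; symmetric variables (HbA1c, fasting glucose, blood
#' pressures, total cholesterol) come from a normal truncated at zero; age is
#' derived as onset + duration (clipped towards the target age range, never
#' more than 2 years from the sum); sex and the two categorical risk factors
#' are independent Bernoulli draws at the target fractions.
#'
#' The function is a pure function of `(spec, seed)`: identical arguments
#' give identical cohorts, and the caller's RNG state is left untouched.
#'
#' @param spec a `cohort_spec`, e.g. [table1_cohort_spec()].
#' @param seed integer random seed (required; there is no global default).
#' @return a tibble with one row per patient and the cohort schema columns.
#' @examples
#' cohort <- generate_cohort(table1_cohort_spec(), seed = 42)
#' table(cohort$group)
#' @export
generate_cohort <- function(spec, seed) {
  validate_cohort_spec(spec)
  cohort <- run_seeded(seed, function() {
    rbind(generate_group("PDR", spec$PDR),
          generate_group("NPDR", spec$NPDR))
  })
  validate_cohort(cohort, context = "generated cohort")
  cohort
}
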