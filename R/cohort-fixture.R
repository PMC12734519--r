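#' Deterministic 58-patient reference cohort
#'
#' Builds, without any randomness, a cohort of 27 PDR and 31 NPDR patients
#' whose dichotomized risk factors reproduce the published univariate
#' analysis exactly:
#'
#' * poor long-term glycaemic control (HbA1c > 7%): 23/27 vs 9/31
#' * irregular ophthalmological examinations: 22/27 vs 4/31
#' * diabetes onset at or before 18 years: 16/27 vs 4/31
#' * diabetes duration above 22.5 years: 20/27 vs 9/31
#' * sex: 12 female / 15 male vs 13 female / 18 male
#'
#' Continuous fields are filled with deterministic values consistent with the
#' assigned categories and the record invariants (durations avoid the 22.5 y
#' split point; the cohort-wide duration median is exactly 22.5).  This is
#' synthetic reference data: only the categorical structure above mirrors the
#' study cohort.
#'
#' @return a 58-row cohort tibble.
#' @examples
#' fx <- fixture_cohort()
#' table(fx$group, fx$longterm_control)
#' @export
fixture_cohort <- function() {
  build_group <- function(group, n, n_female, n_poor, n_irregular,
                          n_onset_le18, n_long_duration,
                          onset_young_base, onset_young_span,
                          hba1c_poor_base, hba1c_good_base) {
    i <- seq_len(n)
    onset_young <- onset_young_base + ((i - 1L) %% onset_young_span)
    onset_old <- 19 + ((i - 1L) %% 11)          # 19..29, all > 18, <= 30
    onset <- ifelse(i <= n_onset_le18, onset_young, onset_old)
    dur_long <- 24 + ((i - 1L) %% 14)           # 24..37, all > 22.5
    dur_short <- 10 + ((i - 1L) %% 12)          # 10..21, all in (5, 22.5)
    duration <- ifelse(i <= n_long_duration, dur_long, dur_short)
    hba1c <- ifelse(i <= n_poor,
                    hba1c_poor_base + 0.1 * ((i - 1L) %% 9),   # all > 7
                    hba1c_good_base + 0.1 * ((i - 1L) %% 9))   # all <= 7
    tibble::tibble(
      patient_id = sprintf("%s-%02d", tolower(group), i),
      group = group,
      sex = ifelse(i <= n_female, "female", "male"),
      age_years = onset + duration,
      onset_age_years = onset,
      duration_years = duration,
      hba1c_current_pct = hba1c,
      fasting_glucose_mmol_l = 5.5 + 0.1 * ((i - 1L) %% 20),
      sbp_mmhg = 125 + ((i - 1L) %% 25),
      dbp_mmhg = 75 + ((i - 1L) %% 15),
      total_chol_mmol_l = 3.5 + 0.1 * ((i - 1L) %% 15),
      ldl_mmol_l = 1.2 + 0.1 * ((i - 1L) %% 25),
      tg_mmol_l = 0.9 + 0.05 * ((i - 1L) %% 30),
      longterm_control = ifelse(i <= n_poor, "poor", "good"),
      exam_regularity = ifelse(i <= n_irregular, "irregular", "regular"))
  }
  cohort <- rbind(
    build_group("PDR", n = 27L, n_female = 12L, n_poor = 23L,
                n_irregular = 22L, n_onset_le18 = 16L, n_long_duration = 20L,
                onset_young_base = 10, onset_young_span = 9L,
                hba1c_poor_base = 7.5, hba1c_good_base = 5.8),
    build_group("NPDR", n = 31L, n_female = 13L, n_poor = 9L,
                n_irregular = 4L, n_onset_le18 = 4L, n_long_duration = 9L,
                onset_young_base = 12, onset_young_span = 7L,
                hba1c_poor_base = 7.4, hba1c_good_base = 5.4))
  validate_cohort(cohort, context = "fixture cohort")
  cohort
}
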