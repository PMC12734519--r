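test_that("generation is a pure function of spec and seed", {
  spec <- table1_cohort_spec(n_pdr = 60, n_npdr = 60)
  a <- generate_cohort(spec, seed = 7)
  b <- generate_cohort(spec, seed = 7)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$duration_years,
                                generate_cohort(spec, seed = 8)$duration_years)))

  # the caller's RNG stream must be untouched
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_cohort(spec, seed = 7))
  expect_identical(runif(3), before)
})

test_that("empty groups and invalid specs are handled", {
  empty <- generate_cohort(table1_cohort_spec(n_pdr = 0, n_npdr = 0), seed = 1)
  expect_identical(nrow(empty), 0L)

  spec <- table1_cohort_spec()
  spec$PDR$sex_female_fraction <- 1.4
  expect_error(generate_cohort(spec, seed = 1), "PDR\\$sex_female_fraction")

  spec <- table1_cohort_spec()
  spec$NPDR$skewed$duration_years <- c(median = 9, min = 10, max = 27)
  expect_error(generate_cohort(spec, seed = 1),
               "NPDR\\$skewed\\$duration_years")

  spec <- table1_cohort_spec()
  spec$PDR$symmetric$hba1c_current_pct <- c(mean = 7.9, sd = 0)
  expect_error(generate_cohort(spec, seed = 1),
               "PDR\\$symmetric\\$hba1c_current_pct")

  expect_error(generate_cohort(table1_cohort_spec(), seed = "a"), "seed")
})

test_that("every generated record satisfies the cohort invariants", {
  spec <- table1_cohort_spec(n_pdr = 300, n_npdr = 300)
  for (seed in 1:5) {
    cohort <- generate_cohort(spec, seed = seed)
    expect_silent(validate_cohort(cohort))
    expect_true(all(cohort$duration_years > 5))
    expect_true(all(cohort$onset_age_years <= 30))
    expect_true(all(abs(cohort$age_years -
                        (cohort$onset_age_years + cohort$duration_years)) <= 2))
    expect_true(all(cohort$tg_mmol_l >= 0))
    expect_false(any(cohort$duration_years == 22.5))
    for (g in c("PDR", "NPDR")) {
      gs <- spec[[g]]
      sub <- cohort[cohort$group == g, ]
      for (v in c("duration_years", "onset_age_years", "ldl_mmol_l",
                  "tg_mmol_l")) {
        tr <- gs$skewed[[v]]
        expect_true(all(sub[[v]] >= tr[["min"]] & sub[[v]] <= tr[["max"]]))
      }
    }
  }
})

test_that("large-sample parameter recovery hits the targets", {
  spec <- table1_cohort_spec(n_pdr = 1e5, n_npdr = 1e5)
  cohort <- generate_cohort(spec, seed = 20260929)
  for (g in c("PDR", "NPDR")) {
    gs <- spec[[g]]
    sub <- cohort[cohort$group == g, ]
    for (v in setdiff(names(gs$skewed), "age_years")) {
      target <- gs$skewed[[v]][["median"]]
      expect_lt(abs(median(sub[[v]]) - target) / target, 0.02,
                label = sprintf("%s %s sample-median relative error", g, v))
    }
    # age is derived from onset + duration; its median is only pinned to the
    # published target up to the 2-year internal-consistency slack
    expect_lt(abs(median(sub$age_years) - gs$skewed$age_years[["median"]]), 2)
    for (v in names(gs$symmetric)) {
      target <- gs$symmetric[[v]][["mean"]]
      expect_lt(abs(mean(sub[[v]]) - target) / target, 0.02,
                label = sprintf("%s %s sample-mean relative error", g, v))
    }
    expect_lt(abs(mean(sub$sex == "female") - gs$sex_female_fraction), 0.01)
    expect_lt(abs(mean(sub$longterm_control == "poor") -
                  gs$longterm_poor_fraction), 0.01)
    expect_lt(abs(mean(sub$exam_regularity == "irregular") -
                  gs$exam_irregular_fraction), 0.01)
  }
})
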