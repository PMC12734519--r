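test_that("cost aggregations are exact to the cent", {
  ci <- cost_inputs()
  expect_identical(per_visit_cost(ci), 76.87)
  expect_identical(annual_treated_cost(ci), 7207.45)

  zero <- cost_inputs(fundus_eur = 0, oct_eur = 0, laser_eur = 0,
                      injection_procedure_eur = 0, drug_eur_per_injection = 0,
                      vitrectomy_eur = 0)
  expect_identical(per_visit_cost(zero), 0)
  expect_identical(annual_treated_cost(zero), 0)

  expect_identical(per_visit_cost(cost_inputs(fundus_eur = 10,
                                              oct_eur = 5.50)), 15.5)
  # dropping the injections removes 5 x 960.82
  expect_identical(annual_treated_cost(cost_inputs(injections_per_year = 0)),
                   2403.35)
  expect_error(cost_inputs(oct_eur = -1), "oct_eur")
  expect_error(cost_inputs(injections_per_year = 2.5), "injections_per_year")
})

test_that("scenario results reproduce the published screening table", {
  ci <- cost_inputs()
  medium <- run_scenario(screening_scenario(uptake = 0.60), ci)
  expect_identical(medium$screened, 6000)
  expect_identical(medium$screening_cost_eur, 461220)
  expect_identical(medium$expected_cases, 2820)
  expect_identical(medium$prevented_cases, 1974)

  high <- run_scenario(screening_scenario(uptake = 0.90), ci)
  expect_identical(high$prevented_cases, 2961)
  expect_identical(high$avoided_treatment_eur, 21341259.45)

  none <- run_scenario(screening_scenario(uptake = 0), ci)
  expect_identical(none$screened, 0)
  expect_identical(none$screening_cost_eur, 0)
  expect_identical(none$avoided_treatment_eur, 0)

  # linearity: doubling the population doubles every count and amount
  base <- run_scenario(screening_scenario(0.6, population = 10000), ci)
  dbl <- run_scenario(screening_scenario(0.6, population = 20000), ci)
  for (col in c("screened", "screening_cost_eur", "expected_cases",
                "prevented_cases", "avoided_treatment_eur",
                "net_of_screening_eur")) {
    expect_identical(dbl[[col]], 2 * base[[col]])
  }

  # biennial screening halves the programme cost, not the prevented cases
  biennial <- run_scenario(screening_scenario(0.6, interval_years = 2), ci)
  expect_identical(biennial$screening_cost_eur, medium$screening_cost_eur / 2)
  expect_identical(biennial$prevented_cases, medium$prevented_cases)

  expect_error(screening_scenario(uptake = 1.2), "uptake")
})

test_that("the scenario grid preserves order and matches single runs", {
  ci <- cost_inputs()
  grid <- scenario_grid(default_scenarios(), ci)
  expect_identical(grid$screening_cost_eur, c(230610, 461220, 691830, 230610))
  expect_identical(grid$prevented_cases[1], 987)
  # every monetary output is an exact multiple of one cent
  for (col in c("screening_cost_eur", "avoided_treatment_eur",
                "net_of_screening_eur")) {
    expect_identical(round(grid[[col]] * 100), grid[[col]] * 100)
  }
  single <- scenario_grid(default_scenarios()[2], ci)
  expect_identical(single, run_scenario(default_scenarios()[[2]], ci))
  empty <- scenario_grid(list(), ci)
  expect_identical(nrow(empty), 0L)
})

test_that("break-even matches the closed-form threshold", {
  ci <- cost_inputs()
  s <- screening_scenario(uptake = 0.60)
  # net >= 0 iff effect >= per-visit cost / (prevalence x treated cost)
  closed <- per_visit_cost(ci) / (0.47 * annual_treated_cost(ci))
  expect_equal(break_even(s, ci, "preventive_effect"), closed,
               tolerance = 1e-4)
  expect_lt(closed, 0.03)

  closed_cost <- per_visit_cost(ci) / (0.47 * 0.70)
  expect_equal(break_even(s, ci, "treated_cost"), closed_cost,
               tolerance = 1e-4)

  hopeless <- screening_scenario(uptake = 0.60, preventive_effect = 0)
  expect_error(break_even(hopeless, ci, "uptake"), "no break-even")
})

test_that("one-way sensitivity sweeps are ordered and monotone", {
  ci <- cost_inputs()
  s <- screening_scenario(uptake = 0.60)
  sweep <- one_way_sensitivity(s, ci, "uptake", 0.3, 0.9, steps = 3)
  expect_equal(sweep$value, c(0.3, 0.6, 0.9))
  expect_identical(sweep$avoided_treatment_eur,
                   c(7113753.15, 14227506.30, 21341259.45))

  eff <- one_way_sensitivity(s, ci, "preventive_effect", 0.1, 0.9, steps = 9)
  expect_true(all(diff(eff$net_of_screening_eur) > 0))

  expect_error(one_way_sensitivity(s, ci, "uptake", 0.5, 0.5, steps = 3),
               "low < high")
  expect_error(one_way_sensitivity(s, ci, "uptake", 0.1, 0.9, steps = 1),
               "steps")
})
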