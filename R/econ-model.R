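# Single-period deterministic budget-impact model for national retinopathy
# screening.  All money is carried as integer euro-cents; displayed values
# round half-up.

#' Cost inputs for the screening model
#'
#' Unit costs and annual utilisation counts, defaulting to the Croatian
#' Institute of Health Insurance tariffs used in the study: a combined
#' screening visit is one fundus photograph (40.16 EUR) plus one OCT
#' examination (36.71 EUR); a treated PDR patient accrues 4 monitoring
#' visits, one laser photocoagulation session (84.32 EUR), five intravitreal
#' anti-VEGF injections (procedure 304.91 EUR + aflibercept 655.91 EUR each)
#' and one day-surgery vitrectomy (2011.55 EUR) per year.
#'
#' @param fundus_eur,oct_eur per-exam costs in euros.
#' @param screening_visits_per_year monitoring visits for a treated patient.
#' @param laser_eur,laser_sessions_per_year laser cost and annual sessions.
#' @param injection_procedure_eur,injections_per_year,drug_eur_per_injection
#'   intravitreal injection procedure cost, annual count, and drug cost.
#' @param vitrectomy_eur,vitrectomies_per_year vitrectomy cost and annual
#'   count.
#' @return a validated list of class `cost_inputs`.
#' @export
cost_inputs <- function(fundus_eur = 40.16, oct_eur = 36.71,
                        screening_visits_per_year = 4,
                        laser_eur = 84.32, laser_sessions_per_year = 1,
                        injection_procedure_eur = 304.91,
                        injections_per_year = 5,
                        drug_eur_per_injection = 655.91,
                        vitrectomy_eur = 2011.55, vitrectomies_per_year = 1) {
  ci <- structure(list(
    fundus_eur = fundus_eur, oct_eur = oct_eur,
    screening_visits_per_year = screening_visits_per_year,
    laser_eur = laser_eur, laser_sessions_per_year = laser_sessions_per_year,
    injection_procedure_eur = injection_procedure_eur,
    injections_per_year = injections_per_year,
    drug_eur_per_injection = drug_eur_per_injection,
    vitrectomy_eur = vitrectomy_eur,
    vitrectomies_per_year = vitrectomies_per_year), class = "cost_inputs")
  for (f in names(ci)) {
    v <- ci[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort_input("cost input `", f, "` must be a single non-negative number")
    }
  }
  for (f in c("screening_visits_per_year", "laser_sessions_per_year",
              "injections_per_year", "vitrectomies_per_year")) {
    if (ci[[f]] != floor(ci[[f]])) {
      abort_input("cost input `", f, "` must be an integer count")
    }
  }
  ci
}

#' Cost of one combined screening visit
#'
#' Fundus photography plus OCT, exact to the cent.
#'
#' @param ci a [cost_inputs()] object.
#' @return cost in euros (76.87 at the default tariffs).
#' @export
per_visit_cost <- function(ci) {
  stopifnot(inherits(ci, "cost_inputs"))
  cents_to_eur(eur_to_cents(ci$fundus_eur) + eur_to_cents(ci$oct_eur))
}

#' Annual cost of treating one PDR patient
#'
#' Monitoring visits at the combined per-visit cost, laser sessions,
#' intravitreal injections (procedure + drug), and vitrectomies, summed in
#' exact cents (7207.45 EUR at the default tariffs).
#'
#' @param ci a [cost_inputs()] object.
#' @return cost in euros per patient per year.
#' @export
annual_treated_cost <- function(ci) {
  stopifnot(inherits(ci, "cost_inputs"))
  visit_c <- eur_to_cents(ci$fundus_eur) + eur_to_cents(ci$oct_eur)
  total_c <- ci$screening_visits_per_year * visit_c +
    ci$laser_sessions_per_year * eur_to_cents(ci$laser_eur) +
    ci$injections_per_year * (eur_to_cents(ci$injection_procedure_eur) +
                              eur_to_cents(ci$drug_eur_per_injection)) +
    ci$vitrectomies_per_year * eur_to_cents(ci$vitrectomy_eur)
  cents_to_eur(total_c)
}

#' Define a screening scenario
#'
#' @param uptake fraction of the modelled population attending screening.
#' @param interval_years screening interval (1 = annual, 2 = biennial).
#' @param population size of the modelled young-onset T1D population.
#' @param pdr_prevalence expected lifetime PDR fraction without screening
#'   (0.47 in the study cohort).
#' @param preventive_effect fractional reduction in PDR cases among the
#'   screened (0.70 in the study model).
#' @param label optional display label.
#' @return a validated list of class `screening_scenario`.
#' @export
screening_scenario <- function(uptake, interval_years = 1,
                               population = 10000, pdr_prevalence = 0.47,
                               preventive_effect = 0.70, label = NULL) {
  s <- structure(list(population = population, uptake = uptake,
                      interval_years = interval_years,
                      pdr_prevalence = pdr_prevalence,
                      preventive_effect = preventive_effect,
                      label = label %||% sprintf(
                        "%s-uptake %d%%",
                        if (interval_years == 1) "annual" else
                          sprintf("every %g years", interval_years),
                        as.integer(round_half_up(100 * uptake)))),
                 class = "screening_scenario")
  for (f in c("uptake", "pdr_prevalence", "preventive_effect")) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort_input("scenario field `", f, "` must be a fraction in [0, 1]")
    }
  }
  if (!is.numeric(s$population) || s$population < 0) {
    abort_input("scenario field `population` must be non-negative")
  }
  if (!is.numeric(s$interval_years) || s$interval_years < 1) {
    abort_input("scenario field `interval_years` must be >= 1")
  }
  s
}

#' The four published screening scenarios
#'
#' Annual screening at 30/60/90% uptake plus biennial screening at 60%
#' uptake, for the modelled population of 10,000.
#'
#' @inheritParams screening_scenario
#' @return list of [screening_scenario()] objects.
#' @export
default_scenarios <- function(population = 10000, pdr_prevalence = 0.47,
                              preventive_effect = 0.70) {
  list(
    screening_scenario(0.30, 1, population, pdr_prevalence, preventive_effect,
                       label = "Annual - Low Uptake (30%)"),
    screening_scenario(0.60, 1, population, pdr_prevalence, preventive_effect,
                       label = "Annual - Medium (60%)"),
    screening_scenario(0.90, 1, population, pdr_prevalence, preventive_effect,
                       label = "Annual - High (90%)"),
    screening_scenario(0.60, 2, population, pdr_prevalence, preventive_effect,
                       label = "Biennial - Medium (60%)"))
}

#' Run one screening scenario
#'
#' Deterministic single-period model: `screened = population x uptake`;
#' the annualised programme cost charges one combined visit per screened
#' person per round (`screened x per-visit cost / interval`); expected PDR
#' cases without screening are `screened x prevalence`; prevented cases are
#' `expected x preventive effect`, rounded half-up to a whole person for
#' display; avoided treatment spending is `prevented x annual treated-patient
#' cost`.  `net_of_screening_eur` additionally subtracts the programme cost
#' (the published "net economic impact" column does not).  The preventive
#' effect is not attenuated for biennial screening; only the annualised
#' programme cost halves.
#'
#' @param s a [screening_scenario()].
#' @param ci a [cost_inputs()] object.
#' @return a one-row tibble: `label`, `screened`, `screening_cost_eur`,
#'   `expected_cases`, `prevented_cases`, `avoided_treatment_eur`,
#'   `net_of_screening_eur`, plus unrounded `expected_cases_raw` and
#'   `prevented_cases_raw`.
#' @examples
#' run_scenario(screening_scenario(uptake = 0.6), cost_inputs())
#' @export
run_scenario <- function(s, ci) {
  stopifnot(inherits(s, "screening_scenario"), inherits(ci, "cost_inputs"))
  screened <- round_half_up(s$population * s$uptake)
  visit_c <- eur_to_cents(per_visit_cost(ci))
  cost_c <- round_half_up(screened * visit_c / s$interval_years)
  expected_raw <- screened * s$pdr_prevalence
  prevented_raw <- expected_raw * s$preventive_effect
  prevented <- round_half_up(prevented_raw)
  avoided_c <- prevented * eur_to_cents(annual_treated_cost(ci))
  tibble::tibble(
    label = s$label,
    screened = screened,
    screening_cost_eur = cents_to_eur(cost_c),
    expected_cases = round_half_up(expected_raw),
    prevented_cases = prevented,
    avoided_treatment_eur = cents_to_eur(avoided_c),
    net_of_screening_eur = cents_to_eur(avoided_c - cost_c),
    expected_cases_raw = expected_raw,
    prevented_cases_raw = prevented_raw)
}

#' Run a list of screening scenarios
#'
#' @param scenarios list of [screening_scenario()] objects (may be empty).
#' @param ci a [cost_inputs()] object.
#' @return tibble with one [run_scenario()] row per scenario, in input order.
#' @export
scenario_grid <- function(scenarios, ci) {
  if (length(scenarios) == 0L) {
    return(run_scenario(screening_scenario(0), ci)[0, ])
  }
  do.call(rbind, lapply(scenarios, run_scenario, ci = ci))
}

# continuous (unrounded) net benefit used by break_even: case rounding is
# disabled so the function of the swept parameter is continuous
net_unrounded <- function(s, ci, overrides = list()) {
  p <- list(population = s$population, uptake = s$uptake,
            interval_years = s$interval_years,
            pdr_prevalence = s$pdr_prevalence,
            preventive_effect = s$preventive_effect,
            treated_cost = annual_treated_cost(ci))
  p[names(overrides)] <- overrides
  screened <- p$population * p$uptake
  screened * (p$pdr_prevalence * p$preventive_effect * p$treated_cost -
              per_visit_cost(ci) / p$interval_years)
}

#' Break-even value of one model parameter
#'
#' Smallest value of the chosen parameter at which the net-of-screening
#' benefit (avoided treatment spending minus programme cost) is
#' non-negative, holding everything else fixed.  Solved by bisection on the
#' unrounded model (integer case rounding disabled for continuity) to a
#' relative tolerance of 1e-6.
#'
#' @param s a [screening_scenario()] giving the fixed parameters.
#' @param ci a [cost_inputs()] object.
#' @param parameter one of `"uptake"`, `"preventive_effect"`,
#'   `"treated_cost"`.
#' @param upper upper end of the admissible range (1 for the fractions;
#'   defaults to 1e7 EUR for `treated_cost`).
#' @return the break-even parameter value; error if the net benefit is
#'   negative over the whole admissible range.
#' @export
break_even <- function(s, ci,
                       parameter = c("uptake", "preventive_effect",
                                     "treated_cost"),
                       upper = NULL) {
  parameter <- match.arg(parameter)
  upper <- upper %||% if (parameter == "treated_cost") 1e7 else 1
  lower <- 0
  f <- function(v) net_unrounded(s, ci, stats::setNames(list(v), parameter))
  if (f(upper) < 0) {
    abort_input("no break-even: net benefit is negative over [",
                lower, ", ", upper, "] for ", parameter)
  }
  if (f(lower) >= 0) return(lower)
  lo <- lower; hi <- upper
  while (hi - lo > 1e-6 * max(1, abs(hi))) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  hi
}

#' One-way sensitivity analysis
#'
#' Sweeps a single scenario parameter over an evenly spaced grid and reports
#' the full scenario result at each value.
#'
#' @param s a [screening_scenario()] giving the fixed parameters.
#' @param ci a [cost_inputs()] object.
#' @param parameter one of `"uptake"`, `"preventive_effect"`,
#'   `"pdr_prevalence"`, `"population"`.
#' @param low,high sweep range, `low < high`.
#' @param steps number of grid points, at least 2.
#' @return tibble sorted by parameter value: `parameter`, `value`, and the
#'   [run_scenario()] columns.
#' @export
one_way_sensitivity <- function(s, ci,
                                parameter = c("uptake", "preventive_effect",
                                              "pdr_prevalence", "population"),
                                low, high, steps = 7) {
  parameter <- match.arg(parameter)
  if (!is.numeric(low) || !is.numeric(high) || !(low < high)) {
    abort_input("invalid sweep range: need low < high")
  }
  if (steps < 2) abort_input("`steps` must be at least 2")
  values <- seq(low, high, length.out = steps)
  rows <- lapply(values, function(v) {
    args <- list(uptake = s$uptake, interval_years = s$interval_years,
                 population = s$population,
                 pdr_prevalence = s$pdr_prevalence,
                 preventive_effect = s$preventive_effect, label = s$label)
    args[[parameter]] <- v
    out <- run_scenario(do.call(screening_scenario, args), ci)
    cbind(tibble::tibble(parameter = parameter, value = v), out)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Render scenario results as an aligned-text table
#'
#' @param grid a tibble from [scenario_grid()].
#' @return character vector of report lines.
#' @export
render_scenario_table <- function(grid) {
  money <- function(x) formatC(x, format = "f", digits = 2, big.mark = ",")
  header <- sprintf("%-28s %10s %16s %10s %10s %18s %18s",
                    "Scenario", "Screened", "Screening cost", "Expected",
                    "Prevented", "Avoided treatment", "Net of screening")
  if (nrow(grid) == 0L) return(header)
  c(header, sprintf("%-28s %10d %16s %10d %10d %18s %18s",
                    grid$label, as.integer(grid$screened),
                    money(grid$screening_cost_eur),
                    as.integer(grid$expected_cases),
                    as.integer(grid$prevented_cases),
                    money(grid$avoided_treatment_eur),
                    money(grid$net_of_screening_eur)))
}
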