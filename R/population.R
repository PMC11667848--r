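# Eligible-patient estimation.
#
# The static models (NCP, AIM, ROROR) use a single prevalence-based count;
# the DCF model builds a per-year schedule of treated patients over the
# remaining patent life, combining a prevalent pool and an incident inflow
# with prescription restrictions, clinical attrition and an uptake curve.

#' Eligible patients for the static pricing models
#'
#' `prevalence_per_million * eu_population / 1e6 * treatment_rate *
#' market_share`, rounded half-up to a whole patient. The market share factor
#' only applies to models that model competition (AIM); NCP and ROROR use 1.
#'
#' @param prevalence_per_million Prevalent patients per million persons.
#' @param eu_population Population of the jurisdiction (persons).
#' @param treatment_rate Fraction of prevalent patients treated, in `[0, 1]`.
#' @param market_share Fraction of treated patients on this product, `(0, 1]`.
#' @return Integer patient count.
#' @examples
#' eligible_patients_static(2.9, 447e6, 0.70)        # 907
#' eligible_patients_static(1.6, 447e6, 0.50, 0.50)  # 179
#' @export
eligible_patients_static <- function(prevalence_per_million, eu_population,
                                     treatment_rate = 1, market_share = 1) {
  check_range(prevalence_per_million, "prevalence_per_million", 0, Inf)
  check_range(eu_population, "eu_population", 0, Inf, lower_open = TRUE)
  check_range(treatment_rate, "treatment_rate", 0, 1)
  check_range(market_share, "market_share", 0, 1, lower_open = TRUE)
  round_half_up(prevalence_per_million * eu_population / 1e6 *
                  treatment_rate * market_share)
}

#' Per-year treated-patient schedule for the DCF model
#'
#' For patent year `t = 1..T` the eligible pool combines a steady-state
#' prevalent stock and an incident inflow, both reduced by prescription
#' restrictions and by a multiplicative clinical factor
#' `response * (1 - failure) * (1 - adverse events) * (1 - contraindications)`:
#'
#' `pool(t) = [prev * (1 - restr_prev) + inc * (1 - restr_inc)] * clinical
#'            * population(t) / 1e6`
#'
#' with `population(t) = eu_population * (1 + growth)^(t-1)`. Treated patients
#' follow the uptake curve `uptake(t) = cap * min(1, t / ramp)` (instant cap
#' when `ramp = 0`); the `eligible` column applies the cap alone, mirroring
#' how scenario tables report "eligible patients" independently of the ramp.
#'
#' @param inputs DCF model inputs (`models$dcf$min` etc. of a `case_config`).
#' @param eu_population Launch-year population (persons).
#' @param patent_years Schedule horizon in years (defaults to
#'   `inputs$patent_years`); non-integers are rounded half-up.
#' @return A `patient_schedule`: a tibble with columns `year`, `population`,
#'   `pool`, `eligible`, `uptake`, `treated`.
#' @examples
#' cfg <- lumasiran_config()
#' sched <- dcf_patient_schedule(cfg$models$dcf$min, 447e6)
#' schedule_mean(sched, "eligible") # ~385 patients
#' @export
dcf_patient_schedule <- function(inputs, eu_population,
                                 patent_years = inputs$patent_years) {
  inputs <- validate_model_inputs(unclass(inputs), "dcf")
  check_range(eu_population, "eu_population", 0, Inf, lower_open = TRUE)
  T_years <- round_half_up(patent_years)
  check_range(T_years, "patent_years", 1, Inf)

  t <- seq_len(T_years)
  clinical <- inputs$response_rate * (1 - inputs$failure_rate) *
    (1 - inputs$adverse_event_rate) * (1 - inputs$contraindication_rate)
  pop_t <- eu_population * (1 + inputs$population_growth)^(t - 1)
  pool <- (inputs$prevalence_per_million * (1 - inputs$restriction_prevalent) +
             inputs$incidence_per_million * (1 - inputs$restriction_incident)) *
    clinical * pop_t / 1e6
  ramp <- inputs$uptake_ramp_years
  uptake <- inputs$uptake_cap * pmin(1, if (ramp < 1) 1 else t / ramp)
  out <- tibble(
    year = t,
    population = pop_t,
    pool = pool,
    eligible = pool * inputs$uptake_cap,
    uptake = uptake,
    treated = pool * uptake
  )
  class(out) <- c("patient_schedule", class(out))
  out
}

#' Mean of a patient schedule
#'
#' Arithmetic mean over the patent years of one column of a
#' [dcf_patient_schedule()] result -- `"treated"` for cash-flow summaries,
#' `"eligible"` for the table-style "average number of eligible patients".
#'
#' @param schedule A `patient_schedule`.
#' @param what Column to average: `"treated"` (default) or `"eligible"`.
#' @return A single number.
#' @export
schedule_mean <- function(schedule, what = c("treated", "eligible")) {
  what <- match.arg(what)
  if (!inherits(schedule, "patient_schedule") || nrow(schedule) == 0) {
    abort("schedule must be a non-empty patient_schedule",
          class = c("omppricer_empty_schedule", "omppricer_error"))
  }
  mean(schedule[[what]])
}
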