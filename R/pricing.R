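# The four cost-based pricing models.
#
# Every model returns a `price_result`: an unrounded price per patient per
# year (PPPPY), the price rounded to the reporting granularity, a named
# additive component breakdown that sums exactly to the price, and the
# intermediate quantities (patient counts, R&D PPPY, break-even price, ...)
# needed to audit the calculation.

new_price_result <- function(model, scenario, price_ppppy, components,
                             intermediates, rounding) {
  stopifnot(abs(sum(components) - price_ppppy) <=
              1e-9 * max(1, abs(price_ppppy)))
  structure(
    list(model = model, scenario = scenario,
         price_ppppy = price_ppppy,
         reported_price = round_half_up(price_ppppy, rounding),
         components = components,
         intermediates = intermediates),
    class = "price_result"
  )
}

#' @export
print.price_result <- function(x, ...) {
  cat(sprintf("<price_result: %s%s>\n", x$model,
              if (is.na(x$scenario)) "" else paste0(", ", x$scenario)))
  cat(sprintf("  price: EUR %s per patient per year (reported EUR %s)\n",
              format(round(x$price_ppppy, 2), big.mark = ","),
              format(x$reported_price, big.mark = ",")))
  for (nm in names(x$components)) {
    cat(sprintf("  %-16s EUR %s\n", nm,
                format(round(x$components[[nm]], 2), big.mark = ",")))
  }
  invisible(x)
}

#' Net present value of a cash-flow stream
#'
#' End-of-year convention: the first element is the undiscounted flow at
#' `t = 0`, subsequent elements are discounted by `(1 + rate)^t`.
#'
#' @param cash_flows Numeric vector of EUR flows, `t = 0` first.
#' @param rate Discount rate per year (> -1).
#' @return NPV in EUR.
#' @examples
#' npv(c(-100, 110), 0.10) # 0
#' @export
npv <- function(cash_flows, rate) {
  check_range(rate, "rate", -1, Inf, lower_open = TRUE)
  sum(cash_flows / (1 + rate)^(seq_along(cash_flows) - 1))
}

#' R&D cost per patient per year
#'
#' The EU-attributable share of a global R&D lump sum, amortised linearly
#' over the eligible patients and the remaining patent years.
#'
#' @param rd_cost_total Global R&D cost per approved product (EUR).
#' @param eu_share EU attribution fraction in (0, 1].
#' @param patients Eligible patient count (>= 1).
#' @param patent_years Remaining patent years (>= 1).
#' @return EUR per patient per year.
#' @examples
#' rd_cost_ppppy(830e6, 0.3585, 907, 14) # ~ EUR 23k
#' @export
rd_cost_ppppy <- function(rd_cost_total, eu_share, patients, patent_years) {
  check_range(rd_cost_total, "rd_cost_total", 0, Inf)
  check_range(eu_share, "eu_share", 0, 1, lower_open = TRUE)
  if (length(patients) != 1 || is.na(patients) || patients < 1) {
    abort("patients must be >= 1", class = c("omppricer_zero_patients",
                                             "omppricer_error"))
  }
  if (length(patent_years) != 1 || is.na(patent_years) || patent_years < 1) {
    abort("patent_years must be >= 1", class = c("omppricer_zero_years",
                                                 "omppricer_error"))
  }
  eu_attributable(rd_cost_total, eu_share) / (patients * patent_years)
}

#' Compose an NCP price from per-patient-year intermediates
#'
#' The NCP composition applied to already-amortised intermediates: the drug
#' cost per patient-year (COGS plus marketing surcharge) is added to the R&D
#' PPPY and a clinical-benefit profit margin is applied on top. Useful for
#' recomputing a price directly from published intermediate rows.
#'
#' @param rd_ppppy R&D cost per patient per year (EUR).
#' @param drug_ppppy Drug (manufacturing + marketing) cost per patient per
#'   year (EUR).
#' @param profit_margin Profit margin fraction in `[0, 1]`.
#' @return List with `price_ppppy` and the additive `components`.
#' @examples
#' ncp_compose(111000, 49000, 0.40)$price_ppppy # 224000
#' @export
ncp_compose <- function(rd_ppppy, drug_ppppy, profit_margin) {
  check_range(rd_ppppy, "rd_ppppy", 0, Inf)
  check_range(drug_ppppy, "drug_ppppy", 0, Inf)
  check_range(profit_margin, "profit_margin", 0, 1)
  base <- rd_ppppy + drug_ppppy
  list(price_ppppy = base * (1 + profit_margin),
       components = c(rd = rd_ppppy, drug = drug_ppppy,
                      profit = base * profit_margin))
}

#' Price under the novel cancer pricing (NCP) model
#'
#' Cost-plus composition: amortised R&D plus drug costs (COGS with a
#' marketing-and-sales surcharge expressed as a fraction of manufacturing),
#' marked up by a profit margin tied to anticipated clinical benefit.
#'
#' @param inputs NCP model inputs (see `lumasiran_config()$models$ncp$min`).
#' @param constants Global constants of the case (`$constants`).
#' @param n_patients Optional pinned patient count overriding the
#'   prevalence-based estimate (used by the fixed-population analysis).
#' @param scenario Optional scenario label stored on the result.
#' @return A `price_result` with components `rd`, `cogs`, `marketing`,
#'   `profit`.
#' @examples
#' cfg <- lumasiran_config()
#' ncp_price(cfg$models$ncp$min, cfg$constants)$reported_price # 87000
#' @export
ncp_price <- function(inputs, constants, n_patients = NULL, scenario = NA) {
  inputs <- validate_model_inputs(unclass(inputs), "ncp")
  patients <- n_patients %||%
    eligible_patients_static(inputs$prevalence_per_million,
                             constants$eu_population, inputs$treatment_rate)
  rd <- rd_cost_ppppy(inputs$rd_cost_total, constants$eu_attribution_share,
                      patients, inputs$patent_years)
  cogs <- inputs$cogs_ppppy
  marketing <- cogs * inputs$marketing_fraction
  base <- rd + cogs + marketing
  profit <- base * inputs$profit_margin
  new_price_result(
    "ncp", scenario, base + profit,
    components = c(rd = rd, cogs = cogs, marketing = marketing,
                   profit = profit),
    intermediates = list(eligible_patients = patients, rd_ppppy = rd,
                         drug_ppppy = cogs + marketing),
    rounding = constants$reporting_rounding
  )
}

#' Price under the AIM model
#'
#' Assumption-driven cost recovery: amortised R&D (lump sums capped at
#' EUR 2.5 billion), a production-and-overhead lump per patient-year, and
#' sales/medical-information costs expressed as a fraction of the R&D PPPY.
#' An 8% basic profit and an innovation bonus (0-40%) are applied on top,
#' either additively (`price = base * (1 + profit + bonus)`, the default) or
#' multiplicatively (`base * (1 + profit) * (1 + bonus)`), controlled by the
#' `bonus_convention` input.
#'
#' @inheritParams ncp_price
#' @param inputs AIM model inputs.
#' @return A `price_result` with components `rd`, `production`, `sales`,
#'   `profit`, `bonus`.
#' @examples
#' cfg <- lumasiran_config()
#' aim_price(cfg$models$aim$min, cfg$constants)$reported_price # 33000
#' @export
aim_price <- function(inputs, constants, n_patients = NULL, scenario = NA) {
  inputs <- validate_model_inputs(unclass(inputs), "aim")
  patients <- n_patients %||%
    eligible_patients_static(inputs$prevalence_per_million,
                             constants$eu_population, inputs$treatment_rate,
                             inputs$market_share)
  rd <- rd_cost_ppppy(inputs$rd_cost_total, constants$eu_attribution_share,
                      patients, inputs$patent_years)
  production <- inputs$production_overhead_ppppy
  sales <- inputs$sales_fraction * rd
  base <- rd + production + sales
  convention <- inputs$bonus_convention %||% "additive"
  profit <- base * inputs$basic_profit
  bonus <- if (convention == "additive") {
    base * inputs$innovation_bonus
  } else {
    (base + profit) * inputs$innovation_bonus
  }
  new_price_result(
    "aim", scenario, base + profit + bonus,
    components = c(rd = rd, production = production, sales = sales,
                   profit = profit, bonus = bonus),
    intermediates = list(eligible_patients = patients, rd_ppppy = rd,
                         bonus_convention = convention),
    rounding = constants$reporting_rounding
  )
}

# Discounted patient-year revenue units: sum over the schedule of
# treated(t) * (1 - drug cost fraction) / (1 + r)^t.
dcf_revenue_units <- function(treated, delta, rate) {
  sum(treated * (1 - delta) / (1 + rate)^(seq_along(treated)))
}

#' Break-even price under the DCF model
#'
#' The unique price at which the net present value of the product's EU cash
#' flows is zero at patent expiry: the EU-attributable R&D lump sum `K` is a
#' sunk outflow at launch (`t = 0`), each patent year earns
#' `price * treated(t) * (1 - delta)` net of drug costs (`delta` = drug cost
#' fraction of revenue), discounted at the cost of capital `r`. Closed form:
#'
#' `P* = K / sum_t[ treated(t) * (1 - delta) / (1 + r)^t ]`
#'
#' @param inputs DCF model inputs.
#' @param constants Global constants of the case.
#' @param n_patients Optional constant per-year treated count overriding the
#'   schedule (fixed-population analysis).
#' @return Break-even price in EUR per patient per year.
#' @examples
#' cfg <- lumasiran_config()
#' dcf_break_even_price(cfg$models$dcf$min, cfg$constants) # ~ EUR 173k
#' @export
dcf_break_even_price <- function(inputs, constants, n_patients = NULL) {
  dcf_core(inputs, constants, n_patients)$break_even
}

dcf_core <- function(inputs, constants, n_patients = NULL) {
  inputs <- validate_model_inputs(unclass(inputs), "dcf")
  T_years <- round_half_up(inputs$patent_years)
  if (is.null(n_patients)) {
    schedule <- dcf_patient_schedule(inputs, constants$eu_population)
    treated <- schedule$treated
  } else {
    schedule <- NULL
    treated <- rep(n_patients, T_years)
  }
  K <- eu_attributable(inputs$rd_lumpsum_total,
                       constants$eu_attribution_share)
  delta <- inputs$drug_cost_fraction_of_revenue
  units <- dcf_revenue_units(treated, delta, inputs$cost_of_capital)
  if (units <= 0) {
    abort("patient schedule generates no discounted revenue",
          class = c("omppricer_no_revenue", "omppricer_error"))
  }
  list(
    inputs = inputs, schedule = schedule, treated = treated, lumpsum_eu = K,
    break_even = K / units,
    break_even_r0 = K / dcf_revenue_units(treated, delta, 0)
  )
}

#' Price under the discounted-cash-flow (DCF) model
#'
#' The break-even price (see [dcf_break_even_price()]) marked up by a fixed
#' innovation premium. The breakdown splits the price into the cost recovery
#' that would be needed with no discounting (`rd_principal`, the break-even
#' price at `r = 0`), the increment attributable to the cost of capital
#' (`cost_of_capital`), and the premium. The drug-cost share of revenue is a
#' deduction inside the break-even calculation and is reported among the
#' intermediates rather than as an additive component.
#'
#' @inheritParams dcf_break_even_price
#' @param scenario Optional scenario label.
#' @return A `price_result` with components `rd_principal`,
#'   `cost_of_capital`, `premium`.
#' @examples
#' cfg <- lumasiran_config()
#' dcf_price(cfg$models$dcf$min, cfg$constants)$reported_price
#' @export
dcf_price <- function(inputs, constants, n_patients = NULL, scenario = NA) {
  core <- dcf_core(inputs, constants, n_patients)
  p_star <- core$break_even
  p0 <- core$break_even_r0
  premium <- p_star * core$inputs$innovation_premium
  new_price_result(
    "dcf", scenario, p_star + premium,
    components = c(rd_principal = p0,
                   cost_of_capital = p_star - p0,
                   premium = premium),
    intermediates = list(
      eligible_patients = mean(core$treated),
      schedule_mean_treated = mean(core$treated),
      schedule_mean_eligible = if (!is.null(core$schedule))
        mean(core$schedule$eligible) else mean(core$treated),
      break_even_price = p_star,
      rd_lumpsum_eu = core$lumpsum_eu,
      drug_cost_share = core$inputs$drug_cost_fraction_of_revenue
    ),
    rounding = constants$reporting_rounding
  )
}

#' Price under the real-option rate-of-return (ROROR) model
#'
#' Amortised R&D is compounded from the investment period to approval at the
#' weighted average cost of capital and deflated by the GDP deflator over the
#' same period, as a single real-terms ratio factor
#' `((1 + wacc) / (1 + deflator))^years_until_approval`. The compounded R&D
#' plus production cost is marked up by a profit margin. The breakdown
#' separates the R&D principal from the compounding increment
#' (`cost_of_capital`).
#'
#' @inheritParams ncp_price
#' @param inputs ROROR model inputs.
#' @return A `price_result` with components `production`, `rd_principal`,
#'   `cost_of_capital`, `profit`.
#' @examples
#' cfg <- lumasiran_config()
#' roror_price(cfg$models$roror$min, cfg$constants)$reported_price
#' @export
roror_price <- function(inputs, constants, n_patients = NULL, scenario = NA) {
  inputs <- validate_model_inputs(unclass(inputs), "roror")
  patients <- n_patients %||%
    eligible_patients_static(inputs$prevalence_per_million,
                             constants$eu_population, inputs$treatment_rate)
  rd <- rd_cost_ppppy(inputs$rd_cost_total, constants$eu_attribution_share,
                      patients, inputs$patent_years)
  factor <- ((1 + inputs$wacc) / (1 + inputs$gdp_deflator))^
    inputs$years_until_approval
  rd_compounded <- rd * factor
  production <- inputs$production_cost_ppppy
  profit <- (production + rd_compounded) * inputs$profit_margin
  new_price_result(
    "roror", scenario, production + rd_compounded + profit,
    components = c(production = production, rd_principal = rd,
                   cost_of_capital = rd_compounded - rd, profit = profit),
    intermediates = list(eligible_patients = patients, rd_ppppy = rd,
                         compounding_factor = factor),
    rounding = constants$reporting_rounding
  )
}

price_fun <- function(model) {
  switch(model, ncp = ncp_price, aim = aim_price, dcf = dcf_price,
         roror = roror_price,
         abort(paste0("unknown model: ", model),
               class = c("omppricer_model_mismatch", "omppricer_error")))
}
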