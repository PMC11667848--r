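# Scenario orchestration: min/max/average runs, one-at-a-time sensitivity,
# the fixed-population supplementary analysis, and cross-model range
# summaries.

scenario_labels <- c("min", "max", "avg")

#' Run the minimum, maximum and average scenarios of one model
#'
#' Prices the minimum-scenario and maximum-scenario input columns of the
#' configuration and an average scenario whose inputs are the field-wise
#' means of the two columns (averaging applies to inputs, never to prices).
#'
#' @param config A `case_config` from [load_config()].
#' @param model One of `"ncp"`, `"aim"`, `"dcf"`, `"roror"`.
#' @return A `scenario_set`: `model` plus a list `results` with one
#'   `price_result` per scenario (`min`, `max`, `avg`). Use [tidy()] /
#'   [glance()] for tabular views.
#' @examples
#' cfg <- lumasiran_config()
#' glance(run_scenarios(cfg, "ncp")) # 87000 / 224000-range prices
#' @export
run_scenarios <- function(config, model = model_ids()) {
  stopifnot(inherits(config, "case_config"))
  model <- match.arg(model)
  cols <- config$models[[model]]
  inputs <- list(min = cols$min, max = cols$max,
                 avg = build_average_inputs(cols$min, cols$max))
  fn <- price_fun(model)
  results <- purrr::imap(inputs,
                         function(inp, scen) fn(inp, config$constants,
                                                scenario = scen))
  structure(list(model = model, results = results), class = "scenario_set")
}

#' Run all four models
#'
#' @param config A `case_config`.
#' @return Named list of `scenario_set`, one per model.
#' @export
run_all_scenarios <- function(config) {
  sets <- purrr::map(model_ids(), function(m) run_scenarios(config, m))
  rlang::set_names(sets, model_ids())
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("<scenario_set:", x$model, "model>\n")
  print(glance(x))
  invisible(x)
}

# One-at-a-time parameter enumeration. Parameters that the scenario tables
# only define jointly (DCF prescription restrictions on the prevalent and
# incident pools) are varied as a single named group.
oat_parameters <- function(model) {
  fields <- names(model_fields[[model]])
  params <- as.list(rlang::set_names(fields))
  if (model == "dcf") {
    grouped <- c("restriction_prevalent", "restriction_incident")
    params <- params[setdiff(fields, grouped)]
    params$prescription_restrictions <- grouped
  }
  params
}

#' One-at-a-time (tornado) sensitivity analysis
#'
#' Starting from the average scenario, each input parameter is substituted in
#' turn with its minimum-column and maximum-column value while all other
#' parameters stay at their averages, and the price is recomputed. Grouped
#' parameters (DCF prescription restrictions) move together. Substituting a
#' parameter's own average reproduces the base price exactly.
#'
#' @param config A `case_config`.
#' @param model Model identifier.
#' @return A tibble (class `oat_sensitivity`) with one row per parameter:
#'   `model`, `parameter`, `base_price`, `price_at_param_min`,
#'   `price_at_param_max` (unrounded EUR) and the bar `width`.
#' @examples
#' cfg <- lumasiran_config()
#' oat_sensitivity(cfg, "ncp")
#' @export
oat_sensitivity <- function(config, model = model_ids()) {
  stopifnot(inherits(config, "case_config"))
  model <- match.arg(model)
  cols <- config$models[[model]]
  avg <- build_average_inputs(cols$min, cols$max)
  fn <- price_fun(model)
  base <- fn(avg, config$constants, scenario = "avg")$price_ppppy

  substitute_price <- function(fields, from) {
    inp <- avg
    for (f in fields) inp[[f]] <- from[[f]]
    fn(validate_model_inputs(unclass(inp), model), config$constants)$price_ppppy
  }
  params <- oat_parameters(model)
  rows <- purrr::imap(params, function(fields, nm) {
    tibble(model = model, parameter = nm, base_price = base,
           price_at_param_min = substitute_price(fields, cols$min),
           price_at_param_max = substitute_price(fields, cols$max))
  })
  out <- dplyr::bind_rows(rows)
  out$width <- abs(out$price_at_param_max - out$price_at_param_min)
  class(out) <- c("oat_sensitivity", class(out))
  out
}

#' Fixed-population supplementary analysis
#'
#' Reprices the minimum and maximum scenarios with the number of treated
#' patients pinned to a constant (default 1000), bypassing the model's own
#' patient estimation: treatment rates, market shares and uptake curves are
#' disregarded. This isolates how much of the inter-model price spread is due
#' to each model's patient-number strategy.
#'
#' @param config A `case_config`.
#' @param model Model identifier.
#' @param n_patients Pinned patient count (>= 1), applied as a constant
#'   per-year schedule for the DCF model.
#' @return A `fixed_population_result`: list with `min` and `max`
#'   `price_result`s.
#' @examples
#' cfg <- lumasiran_config()
#' fixed_population_analysis(cfg, "ncp")$min$price_ppppy # ~ EUR 84.8k
#' @export
fixed_population_analysis <- function(config, model = model_ids(),
                                      n_patients = 1000) {
  stopifnot(inherits(config, "case_config"))
  model <- match.arg(model)
  if (n_patients < 1) {
    abort("n_patients must be >= 1",
          class = c("omppricer_zero_patients", "omppricer_error"))
  }
  fn <- price_fun(model)
  out <- purrr::imap(
    list(min = config$models[[model]]$min, max = config$models[[model]]$max),
    function(inp, scen) fn(inp, config$constants, n_patients = n_patients,
                           scenario = scen)
  )
  structure(c(out, list(model = model, n_patients = n_patients)),
            class = "fixed_population_result")
}

#' Overlap of reported price ranges across models
#'
#' The interval spanned by all model ranges simultaneously:
#' `[max of reported minima, min of reported maxima]`, or an empty marker
#' when the ranges do not intersect.
#'
#' @param scenario_sets List of at least two `scenario_set` objects.
#' @return A one-row tibble with `lower`, `upper` and `overlaps` (logical;
#'   when `FALSE` the interval is empty and `lower > upper`).
#' @examples
#' cfg <- lumasiran_config()
#' range_overlap(run_all_scenarios(cfg))
#' @export
range_overlap <- function(scenario_sets) {
  stopifnot(length(scenario_sets) >= 2)
  minima <- purrr::map_dbl(scenario_sets,
                           function(s) s$results$min$reported_price)
  maxima <- purrr::map_dbl(scenario_sets,
                           function(s) s$results$max$reported_price)
  lower <- max(minima)
  upper <- min(maxima)
  tibble(lower = lower, upper = upper, overlaps = lower <= upper)
}
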