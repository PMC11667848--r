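# broom-style tidiers for result objects.

#' Tidy a price result into its component breakdown
#'
#' @param x A `price_result`.
#' @param ... Unused.
#' @return A tibble with one row per additive component: `model`, `scenario`,
#'   `component`, `eur`, `share` (fraction of the unrounded price).
#' @examples
#' cfg <- lumasiran_config()
#' tidy(ncp_price(cfg$models$ncp$min, cfg$constants))
#' @export
tidy.price_result <- function(x, ...) {
  tibble(
    model = x$model,
    scenario = as.character(x$scenario),
    component = names(x$components),
    eur = unname(x$components),
    share = unname(x$components) / x$price_ppppy
  )
}

#' One-row summary of a price result
#'
#' @param x A `price_result`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `scenario`, `eligible_patients`,
#'   `rd_ppppy` (where defined), `price_ppppy`, `reported_price`.
#' @export
glance.price_result <- function(x, ...) {
  tibble(
    model = x$model,
    scenario = as.character(x$scenario),
    eligible_patients = x$intermediates$eligible_patients,
    rd_ppppy = x$intermediates$rd_ppppy %||% NA_real_,
    price_ppppy = x$price_ppppy,
    reported_price = x$reported_price
  )
}

#' Tidy a scenario set
#'
#' @param x A `scenario_set` from [run_scenarios()].
#' @param ... Unused.
#' @return Component breakdowns of the three scenarios, stacked.
#' @export
tidy.scenario_set <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$results, tidy))
}

#' One row per scenario of a scenario set
#'
#' @param x A `scenario_set`.
#' @param ... Unused.
#' @return A three-row tibble (min, max, avg) of price summaries.
#' @export
glance.scenario_set <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$results, glance))
}

#' Tidy a fixed-population analysis
#'
#' @param x A `fixed_population_result`.
#' @param ... Unused.
#' @return A two-row tibble (min and max scenario at the pinned patient
#'   count).
#' @export
tidy.fixed_population_result <- function(x, ...) {
  out <- dplyr::bind_rows(glance(x$min), glance(x$max))
  out$n_patients <- x$n_patients
  out
}
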