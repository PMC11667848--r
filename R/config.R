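# Case configuration: loading, validation, normalisation.
#
# A case configuration holds, for one medicine, the full parameterisation of
# the four pricing models: a minimum-scenario and a maximum-scenario input
# column per model, plus global constants (EU population, EU cost-attribution
# share, USD->EUR rate, reporting granularity). The scenario columns follow
# the orientation convention of the source tables: the "minimum" column holds
# the price-minimising end of each parameter (e.g. the highest patient count),
# the "maximum" column the price-maximising end.

# field registry ------------------------------------------------------------
# lower/upper: admissible range (open bounds flagged); dir: sign of the price
# response used to orient synthetic scenario columns (+1 price-raising).

fld <- function(lower, upper, dir, lower_open = FALSE, upper_open = FALSE,
                integer = FALSE, monetary = FALSE) {
  list(lower = lower, upper = upper, dir = dir, lower_open = lower_open,
       upper_open = upper_open, integer = integer, monetary = monetary)
}

model_fields <- list(
  ncp = list(
    prevalence_per_million = fld(0, Inf, -1),
    treatment_rate         = fld(0, 1, -1),
    patent_years           = fld(1, Inf, -1, integer = TRUE),
    rd_cost_total          = fld(0, Inf, +1, monetary = TRUE),
    cogs_ppppy             = fld(0, Inf, +1, monetary = TRUE),
    marketing_fraction     = fld(0, Inf, +1),
    profit_margin          = fld(0, 1, +1)
  ),
  aim = list(
    prevalence_per_million    = fld(0, Inf, -1),
    treatment_rate            = fld(0, 1, -1),
    market_share              = fld(0, 1, -1, lower_open = TRUE),
    patent_years              = fld(1, Inf, -1, integer = TRUE),
    rd_cost_total             = fld(0, 2.5e9, +1, monetary = TRUE),
    production_overhead_ppppy = fld(0, Inf, +1, monetary = TRUE),
    sales_fraction            = fld(0, Inf, +1),
    basic_profit              = fld(0, 1, +1),
    innovation_bonus          = fld(0, 1, +1)
  ),
  dcf = list(
    prevalence_per_million        = fld(0, Inf, -1),
    incidence_per_million         = fld(0, Inf, -1),
    response_rate                 = fld(0, 1, -1),
    failure_rate                  = fld(0, 1, +1),
    adverse_event_rate            = fld(0, 1, +1),
    contraindication_rate         = fld(0, 1, +1),
    restriction_prevalent         = fld(0, 1, +1),
    restriction_incident          = fld(0, 1, +1),
    population_growth             = fld(-0.5, 0.5, -1),
    uptake_cap                    = fld(0, 1, -1, lower_open = TRUE),
    uptake_ramp_years             = fld(0, Inf, +1, integer = TRUE),
    patent_years                  = fld(1, Inf, -1, integer = TRUE),
    rd_lumpsum_total              = fld(0, Inf, +1, monetary = TRUE),
    drug_cost_fraction_of_revenue = fld(0, 1, +1, upper_open = TRUE),
    cost_of_capital               = fld(0, 1, +1),
    innovation_premium            = fld(0, 1, +1)
  ),
  roror = list(
    prevalence_per_million = fld(0, Inf, -1),
    treatment_rate         = fld(0, 1, -1),
    patent_years           = fld(1, Inf, -1, integer = TRUE),
    rd_cost_total          = fld(0, Inf, +1, monetary = TRUE),
    production_cost_ppppy  = fld(0, Inf, +1, monetary = TRUE),
    wacc                   = fld(0, 1, +1),
    gdp_deflator           = fld(0, 1, -1),
    years_until_approval   = fld(0, Inf, +1),
    profit_margin          = fld(0, 1, +1)
  )
)

# structural (non-numeric) fields copied verbatim and required to agree
# between scenario columns
structural_fields <- list(
  ncp = character(0),
  aim = "bonus_convention",
  dcf = character(0),
  roror = character(0)
)

model_ids <- function() names(model_fields)

constant_fields <- c("eu_population", "eu_attribution_share",
                     "usd_to_eur_rate", "reporting_rounding")

# constructors --------------------------------------------------------------

new_model_inputs <- function(model, fields) {
  structure(fields, class = c(paste0(model, "_inputs"), "omp_inputs"),
            model = model)
}

#' @export
print.omp_inputs <- function(x, ...) {
  cat("<", attr(x, "model"), " model inputs>\n", sep = "")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

validate_model_inputs <- function(inputs, model, where = model) {
  spec <- model_fields[[model]]
  for (nm in names(spec)) {
    f <- spec[[nm]]
    check_range(inputs[[nm]], paste0(where, ".", nm),
                f$lower, f$upper, f$lower_open, f$upper_open)
  }
  extra <- setdiff(names(inputs), c(names(spec), structural_fields[[model]]))
  if (length(extra)) stop_unknown_key(paste0(where, ".", extra[1]))
  if (model == "aim") {
    bc <- inputs$bonus_convention %||% "additive"
    if (!bc %in% c("additive", "multiplicative")) {
      abort(paste0("`", where, ".bonus_convention` must be 'additive' or ",
                   "'multiplicative'"),
            class = c("omppricer_out_of_range", "omppricer_error"))
    }
    inputs$bonus_convention <- bc
  }
  new_model_inputs(model, inputs[c(names(spec),
                                   intersect(structural_fields[[model]],
                                             names(inputs)))])
}

validate_constants <- function(constants) {
  check_range(constants$eu_population, "constants.eu_population", 0, Inf,
              lower_open = TRUE)
  check_range(constants$eu_attribution_share, "constants.eu_attribution_share",
              0, 1, lower_open = TRUE)
  check_range(constants$usd_to_eur_rate, "constants.usd_to_eur_rate", 0, Inf,
              lower_open = TRUE)
  check_range(constants$reporting_rounding, "constants.reporting_rounding",
              0, Inf, lower_open = TRUE)
  extra <- setdiff(names(constants), constant_fields)
  if (length(extra)) stop_unknown_key(paste0("constants.", extra[1]))
  constants[constant_fields]
}

# currency + attribution helpers -------------------------------------------

#' Convert a US dollar amount to euro
#'
#' Costs quoted in USD (for instance aggregates from US SEC filings) are
#' converted once, at configuration load time, with a fixed annual-average
#' exchange rate.
#'
#' @param amount_usd Non-negative amount in USD.
#' @param rate Exchange rate in EUR per USD (> 0).
#' @return Amount in EUR (`amount_usd * rate`).
#' @examples
#' usd_to_eur(1000, 0.8458)
#' @export
usd_to_eur <- function(amount_usd, rate) {
  if (any(amount_usd < 0)) {
    abort("USD amount must be non-negative",
          class = c("omppricer_negative_amount", "omppricer_error"))
  }
  check_range(rate, "rate", 0, Inf, lower_open = TRUE)
  amount_usd * rate
}

#' EU-attributable share of a global cost
#'
#' Global R&D lump sums are attributed to the EU market in proportion to the
#' EU population among developed countries (35.85% in the bundled case).
#'
#' @param global_cost Non-negative global cost in EUR.
#' @param share Attribution fraction in (0, 1].
#' @return EUR attributable to the EU: `global_cost * share`.
#' @examples
#' eu_attributable(637e6, 0.3585) # ~ EUR 228 million
#' @export
eu_attributable <- function(global_cost, share) {
  if (any(global_cost < 0)) {
    abort("global cost must be non-negative",
          class = c("omppricer_negative_amount", "omppricer_error"))
  }
  check_range(share, "share", 0, 1, lower_open = TRUE)
  global_cost * share
}

#' Average R&D spend per approved product
#'
#' Aggregated company R&D expenditure divided by the number of approved
#' products, so that the cost of failed projects is carried by the approved
#' ones.
#'
#' @param total_rd_spend Non-negative aggregate R&D spend in EUR.
#' @param n_approved_products Integer count of approved products (>= 1).
#' @return EUR per approved product.
#' @examples
#' average_rd_per_product(2.49e9, 3)
#' @export
average_rd_per_product <- function(total_rd_spend, n_approved_products) {
  if (any(total_rd_spend < 0)) {
    abort("total R&D spend must be non-negative",
          class = c("omppricer_negative_amount", "omppricer_error"))
  }
  if (length(n_approved_products) != 1 || n_approved_products < 1 ||
      n_approved_products != as.integer(n_approved_products)) {
    abort("n_approved_products must be a positive integer",
          class = c("omppricer_zero_products", "omppricer_error"))
  }
  total_rd_spend / n_approved_products
}

#' Average two scenario input columns
#'
#' Builds the average-scenario inputs by taking, field by field, the
#' arithmetic mean of the minimum-scenario and maximum-scenario values.
#' Averaging happens on inputs, not on prices: the average-scenario price is
#' recomputed from these averaged inputs. Structural fields (such as the AIM
#' bonus convention) must agree between the two columns and are copied.
#'
#' @param min_inputs,max_inputs Model inputs of the same model, as stored in a
#'   [load_config()] result under `models$<model>$min` / `$max`.
#' @return Averaged model inputs of the same class.
#' @examples
#' cfg <- lumasiran_config()
#' avg <- build_average_inputs(cfg$models$ncp$min, cfg$models$ncp$max)
#' avg$prevalence_per_million # 2.25
#' @export
build_average_inputs <- function(min_inputs, max_inputs) {
  model <- attr(min_inputs, "model")
  if (is.null(model) || !identical(model, attr(max_inputs, "model"))) {
    abort("min and max inputs must come from the same model",
          class = c("omppricer_model_mismatch", "omppricer_error"))
  }
  out <- min_inputs
  for (nm in names(model_fields[[model]])) {
    out[[nm]] <- (min_inputs[[nm]] + max_inputs[[nm]]) / 2
  }
  for (nm in structural_fields[[model]]) {
    if (!identical(min_inputs[[nm]], max_inputs[[nm]])) {
      abort(paste0("structural field `", nm, "` differs between scenarios"),
            class = c("omppricer_model_mismatch", "omppricer_error"))
    }
  }
  validate_model_inputs(unclass(out), model)
}

# load / write --------------------------------------------------------------

resolve_monetary <- function(value, field, rate) {
  if (is.list(value)) {
    extra <- setdiff(names(value), c("value", "currency"))
    if (length(extra)) stop_unknown_key(paste0(field, ".", extra[1]))
    if (is.null(value$value)) stop_missing_key(paste0(field, ".value"))
    cur <- value$currency %||% "EUR"
    if (cur == "USD") return(usd_to_eur(value$value, rate))
    if (cur == "EUR") return(value$value)
    abort(paste0("unsupported currency for `", field, "`: ", cur),
          class = c("omppricer_parse", "omppricer_error"))
  }
  value
}

#' Load and validate a case configuration
#'
#' Reads a YAML or JSON case file, applies an optional overlay (a partial
#' config whose values replace the base, e.g. higher-precision cost figures),
#' converts USD-flagged monetary fields to EUR, and validates every field
#' against its admissible range. The schema is strict: unknown keys are
#' rejected so that transcription typos in table-derived fixtures surface
#' immediately.
#'
#' Monetary fields (`rd_cost_total`, `rd_lumpsum_total`, `cogs_ppppy`,
#' `production_overhead_ppppy`, `production_cost_ppppy`) may be written either
#' as a bare EUR number or as `{value: <x>, currency: USD}`, in which case the
#' amount is converted with `constants$usd_to_eur_rate` at load time.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` case file.
#' @param overlay Optional path to a partial config merged over the base
#'   before validation.
#' @return A validated `case_config`: a list with elements `metadata`,
#'   `constants` and `models` (each model holding `min` and `max` input sets).
#' @examples
#' cfg <- lumasiran_config()
#' cfg$models$ncp$min$prevalence_per_million # 2.9
#' @export
load_config <- function(path, overlay = NULL) {
  raw <- read_config_file(path)
  if (!is.null(overlay)) {
    raw <- modify_deep(raw, read_config_file(overlay))
  }
  validate_config(raw)
}

read_config_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = c("omppricer_parse", "omppricer_error"))
  }
  parsed <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) {
      abort(paste0("cannot parse config file: ", conditionMessage(e)),
            class = c("omppricer_parse", "omppricer_error"))
    }
  )
  if (!is.list(parsed)) {
    abort("config file must contain a mapping at the top level",
          class = c("omppricer_parse", "omppricer_error"))
  }
  parsed
}

modify_deep <- function(base, patch) {
  for (nm in names(patch)) {
    if (is.list(patch[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(patch[[nm]]))) {
      base[[nm]] <- modify_deep(base[[nm]], patch[[nm]])
    } else {
      base[[nm]] <- patch[[nm]]
    }
  }
  base
}

#' Validate a raw case configuration
#'
#' Applies the strict schema checks of [load_config()] to an already-parsed
#' list (useful for programmatically built configs).
#'
#' @param raw A list with elements `metadata`, `constants`, `models`.
#' @return A validated `case_config` object.
#' @export
validate_config <- function(raw) {
  extra <- setdiff(names(raw), c("metadata", "constants", "models"))
  if (length(extra)) stop_unknown_key(extra[1])
  for (key in c("metadata", "constants", "models")) {
    if (is.null(raw[[key]])) stop_missing_key(key)
  }
  if (!is.list(raw$metadata) || !length(raw$metadata)) {
    abort("metadata must be a non-empty mapping",
          class = c("omppricer_missing_key", "omppricer_error"))
  }
  constants <- validate_constants(raw$constants)
  rate <- constants$usd_to_eur_rate

  extra <- setdiff(names(raw$models), model_ids())
  if (length(extra)) stop_unknown_key(paste0("models.", extra[1]))
  models <- list()
  for (m in model_ids()) {
    block <- raw$models[[m]]
    if (is.null(block)) stop_missing_key(paste0("models.", m))
    extra <- setdiff(names(block), c("min", "max"))
    if (length(extra)) stop_unknown_key(paste0("models.", m, ".", extra[1]))
    cols <- list()
    for (scen in c("min", "max")) {
      inp <- block[[scen]]
      if (is.null(inp)) stop_missing_key(paste0("models.", m, ".", scen))
      where <- paste0("models.", m, ".", scen)
      for (nm in names(inp)) {
        if (isTRUE(model_fields[[m]][[nm]]$monetary)) {
          inp[[nm]] <- resolve_monetary(inp[[nm]], paste0(where, ".", nm), rate)
        }
      }
      cols[[scen]] <- validate_model_inputs(inp, m, where)
    }
    models[[m]] <- cols
  }
  structure(list(metadata = raw$metadata, constants = constants,
                 models = models),
            class = "case_config")
}

#' Write a case configuration to YAML
#'
#' The written file round-trips: `load_config(write_config(cfg, path))`
#' reproduces an identical configuration.
#'
#' @param config A `case_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "case_config"))
  plain <- list(
    metadata = config$metadata,
    constants = config$constants,
    models = purrr::map(config$models, function(cols) {
      purrr::map(cols, function(inp) lapply(unclass(inp), identity))
    })
  )
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @export
print.case_config <- function(x, ...) {
  cat("<case_config>", x$metadata$medicine %||% "", "\n")
  cat("  constants: EU population", format(x$constants$eu_population,
                                           big.mark = ","),
      "| EU share", x$constants$eu_attribution_share, "\n")
  cat("  models:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

#' Bundled lumasiran case configuration
#'
#' The lumasiran (primary hyperoxaluria type 1) case shipped with the
#' package: minimum- and maximum-scenario inputs for all four pricing models,
#' transcribed from public scenario tables. With `unrounded = TRUE` a small
#' overlay replaces two "~"-rounded R&D lump sums with the higher-precision
#' values implied by the printed per-patient intermediates.
#'
#' @param unrounded Apply the higher-precision R&D overlay (default `FALSE`).
#' @return A validated `case_config`.
#' @examples
#' cfg <- lumasiran_config()
#' run_scenarios(cfg, "ncp")
#' @export
lumasiran_config <- function(unrounded = FALSE) {
  base <- system.file("extdata", "lumasiran.yaml", package = "omppricer",
                      mustWork = TRUE)
  overlay <- if (unrounded) {
    system.file("extdata", "lumasiran_unrounded.yaml", package = "omppricer",
                mustWork = TRUE)
  }
  load_config(base, overlay = overlay)
}
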