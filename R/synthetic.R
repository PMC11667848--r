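# Synthetic admissible inputs for property testing.
#
# Draws random but admissible parameter sets with the structure the analysis
# assumes (prevalence/incidence per million, rates in [0,1], log-uniform R&D
# lump sums, integer patent years), so invariant and monotonicity suites run
# with no external data. A single integer seed controls one generator
# stream; per-model substreams are derived by fixed offsets so adding a
# model never shifts another model's draws.

#' Sampling ranges for synthetic model inputs
#'
#' Per-parameter sampling intervals used by [sample_inputs()] and
#' [sample_config()]. Defaults reflect plausible orphan-medicine magnitudes:
#' prevalence 0.1-30 per million, incidence 0-2 per million per year, rates
#' uniform on `[0, 1]` with treatment response at least 0.5, integer patent
#' years 1-20, R&D lump sums log-uniform between EUR 50 million and the
#' EUR 2.5 billion cap, per-patient-year unit costs EUR 1k-200k, cost of
#' capital and WACC 0-20%, GDP deflator 0-8%, margins and bonuses 0-50%.
#'
#' @param ... Named overrides, each a length-2 numeric `c(lower, upper)`.
#' @return A named list of sampling intervals (class `synthetic_ranges`).
#' @examples
#' synthetic_ranges(prevalence = c(1, 5))
#' @export
synthetic_ranges <- function(...) {
  defaults <- list(
    prevalence = c(0.1, 30),
    incidence = c(0, 2),
    rate = c(0, 1),
    response = c(0.5, 1),
    patent_years = c(1, 20),
    rd_total = c(50e6, 2.5e9),
    unit_cost = c(1e3, 2e5),
    coc = c(0, 0.20),
    deflator = c(0, 0.08),
    margin = c(0, 0.5),
    growth = c(0, 0.02),
    uptake_cap = c(0.05, 1),
    uptake_ramp_years = c(0, 10),
    years_until_approval = c(0, 15),
    drug_cost_fraction = c(0, 0.8)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop_unknown_key(paste0("ranges.", unknown[1]))
  for (nm in names(overrides)) {
    iv <- overrides[[nm]]
    if (length(iv) != 2 || !is.numeric(iv) || iv[1] > iv[2]) {
      stop_out_of_range(paste0("ranges.", nm), iv[1], iv)
    }
    defaults[[nm]] <- iv
  }
  structure(defaults, class = "synthetic_ranges")
}

# substream offsets (kept well below 2^31 when added to a small seed)
model_seed_offset <- c(ncp = 0L, aim = 1000003L, dcf = 2000003L,
                       roror = 3000017L, config = 4000037L)

with_substream <- function(seed, offset, code) {
  seed <- (as.integer(seed) + offset) %% .Machine$integer.max
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

runif1 <- function(iv) stats::runif(1, iv[1], iv[2])
rlogunif1 <- function(iv) exp(stats::runif(1, log(iv[1]), log(iv[2])))
rint1 <- function(iv) {
  vals <- seq(iv[1], iv[2])
  vals[sample.int(length(vals), 1)]
}

draw_fields <- function(model, ranges) {
  r <- ranges
  switch(model,
    ncp = list(
      prevalence_per_million = runif1(r$prevalence),
      treatment_rate = runif1(r$rate),
      patent_years = rint1(r$patent_years),
      rd_cost_total = rlogunif1(r$rd_total),
      cogs_ppppy = runif1(r$unit_cost),
      marketing_fraction = runif1(r$margin),
      profit_margin = runif1(r$margin)
    ),
    aim = list(
      prevalence_per_million = runif1(r$prevalence),
      treatment_rate = runif1(r$rate),
      market_share = runif1(c(max(r$rate[1], 0.01), r$rate[2])),
      patent_years = rint1(r$patent_years),
      rd_cost_total = rlogunif1(r$rd_total),
      production_overhead_ppppy = runif1(r$unit_cost),
      sales_fraction = runif1(r$margin),
      basic_profit = runif1(r$margin),
      innovation_bonus = runif1(r$margin),
      bonus_convention = "additive"
    ),
    dcf = list(
      prevalence_per_million = runif1(r$prevalence),
      incidence_per_million = runif1(r$incidence),
      response_rate = runif1(r$response),
      failure_rate = runif1(c(0, 0.5)),
      adverse_event_rate = runif1(c(0, 0.5)),
      contraindication_rate = runif1(c(0, 0.5)),
      restriction_prevalent = runif1(c(0, 0.9)),
      restriction_incident = runif1(c(0, 0.9)),
      population_growth = runif1(r$growth),
      uptake_cap = runif1(r$uptake_cap),
      uptake_ramp_years = rint1(r$uptake_ramp_years),
      patent_years = rint1(r$patent_years),
      rd_lumpsum_total = rlogunif1(r$rd_total),
      drug_cost_fraction_of_revenue = runif1(r$drug_cost_fraction),
      cost_of_capital = runif1(r$coc),
      innovation_premium = runif1(r$margin)
    ),
    roror = list(
      prevalence_per_million = runif1(r$prevalence),
      treatment_rate = runif1(r$rate),
      patent_years = rint1(r$patent_years),
      rd_cost_total = rlogunif1(r$rd_total),
      production_cost_ppppy = runif1(r$unit_cost),
      wacc = runif1(r$coc),
      gdp_deflator = runif1(r$deflator),
      years_until_approval = rint1(r$years_until_approval),
      profit_margin = runif1(r$margin)
    )
  )
}

inputs_admissible <- function(model, fields, eu_population) {
  ok <- tryCatch({
    validate_model_inputs(fields, model)
    TRUE
  }, omppricer_error = function(e) FALSE)
  if (!ok) return(FALSE)
  if (model == "dcf") {
    sched <- dcf_patient_schedule(validate_model_inputs(fields, "dcf"),
                                  eu_population)
    sum(sched$treated) >= 1
  } else {
    eligible_patients_static(
      fields$prevalence_per_million, eu_population, fields$treatment_rate,
      fields$market_share %||% 1) >= 1
  }
}

#' Draw one admissible synthetic input set
#'
#' Deterministic given `seed`: the same seed always yields the same inputs.
#' Draws are resampled (bounded retries) until the implied eligible patient
#' count is at least one.
#'
#' @param model Model identifier (`"ncp"`, `"aim"`, `"dcf"`, `"roror"`).
#' @param seed Integer seed.
#' @param ranges A [synthetic_ranges()] object.
#' @param eu_population Population used for the patient-count admissibility
#'   check.
#' @return Validated model inputs.
#' @examples
#' sample_inputs("ncp", seed = 1)
#' @export
sample_inputs <- function(model = model_ids(), seed, ranges = synthetic_ranges(),
                          eu_population = 447e6) {
  model <- match.arg(model)
  stopifnot(inherits(ranges, "synthetic_ranges"))
  with_substream(seed, model_seed_offset[[model]], {
    for (i in 1:100) {
      fields <- draw_fields(model, ranges)
      if (inputs_admissible(model, fields, eu_population)) {
        return(validate_model_inputs(fields, model))
      }
    }
    abort("could not draw admissible inputs in 100 tries",
          class = c("omppricer_exhausted_retries", "omppricer_error"))
  })
}

# Orient a pair of draws into scenario columns: the minimum-price column
# takes the price-lowering end of the parameter (dir = +1 means the price
# rises with the parameter, so the min column takes the smaller draw).
orient_pair <- function(a, b, dir) {
  lo <- min(a, b); hi <- max(a, b)
  if (dir > 0) c(min = lo, max = hi) else c(min = hi, max = lo)
}

#' Draw a full synthetic case configuration
#'
#' Samples two admissible values per parameter and orients them into
#' minimum- and maximum-price scenario columns following the table
#' convention: parameters that lower the price (e.g. a larger patient pool)
#' put their larger value in the minimum column. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param ranges A [synthetic_ranges()] object.
#' @param constants Global constants for the synthetic case.
#' @return A validated `case_config`.
#' @examples
#' cfg <- sample_config(seed = 7)
#' glance(run_scenarios(cfg, "aim"))
#' @export
sample_config <- function(seed, ranges = synthetic_ranges(),
                          constants = list(eu_population = 447e6,
                                           eu_attribution_share = 0.3585,
                                           usd_to_eur_rate = 0.8458,
                                           reporting_rounding = 1000)) {
  stopifnot(inherits(ranges, "synthetic_ranges"))
  models <- list()
  for (m in model_ids()) {
    cols <- NULL
    for (attempt in 0:99) {
      shift <- attempt * 700001L
      a <- unclass(sample_inputs(m, seed + shift, ranges,
                                 constants$eu_population))
      b <- unclass(sample_inputs(m, seed + shift + 500009L, ranges,
                                 constants$eu_population))
      cand <- list(min = a, max = a)
      for (nm in names(model_fields[[m]])) {
        pair <- orient_pair(a[[nm]], b[[nm]], model_fields[[m]][[nm]]$dir)
        cand$min[[nm]] <- unname(pair["min"])
        cand$max[[nm]] <- unname(pair["max"])
      }
      avg <- purrr::map2(cand$min, cand$max,
                         function(x, y) if (is.numeric(x)) (x + y) / 2 else x)
      ok <- all(purrr::map_lgl(list(cand$min, cand$max, avg),
                               function(col)
                                 inputs_admissible(m, col,
                                                   constants$eu_population)))
      if (ok) { cols <- cand; break }
    }
    if (is.null(cols)) {
      abort("could not orient admissible scenario columns in 100 tries",
            class = c("omppricer_exhausted_retries", "omppricer_error"))
    }
    models[[m]] <- cols
  }
  validate_config(list(
    metadata = list(medicine = "synthetic",
                    note = paste0("sampled with seed ", seed)),
    constants = constants,
    models = models
  ))
}
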