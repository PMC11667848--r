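test_that("scenario runs reproduce the published NCP and AIM prices", {
  cfg <- lumasiran_config()
  ncp <- glance(run_scenarios(cfg, "ncp"))
  expect_equal(ncp$reported_price[ncp$scenario == "min"], 87000)
  expect_equal(ncp$reported_price[ncp$scenario == "avg"], 126000)
  # published 224000 composes from printed (rounded) intermediates; the full
  # chain from raw inputs lands one rounding step below
  expect_lte(abs(ncp$reported_price[ncp$scenario == "max"] - 224000), 1000)

  aim <- glance(run_scenarios(cfg, "aim"))
  expect_equal(aim$reported_price[aim$scenario == "min"], 33000)
})

test_that("unrounded min <= avg <= max for every model on the fixture", {
  cfg <- lumasiran_config()
  for (m in c("ncp", "aim", "dcf", "roror")) {
    g <- glance(run_scenarios(cfg, m))
    p <- setNames(g$price_ppppy, g$scenario)
    expect_lte(p["min"], p["avg"])
    expect_lte(p["avg"], p["max"])
  }
})

test_that("identical scenario columns give three identical results", {
  cfg <- lumasiran_config()
  cfg$models$ncp$max <- cfg$models$ncp$min
  g <- glance(run_scenarios(cfg, "ncp"))
  expect_equal(length(unique(g$price_ppppy)), 1L)
})

test_that("OAT varies the documented per-model parameter sets", {
  cfg <- lumasiran_config()
  expect_equal(nrow(oat_sensitivity(cfg, "ncp")), 7)
  expect_equal(nrow(oat_sensitivity(cfg, "aim")), 9)
  expect_equal(nrow(oat_sensitivity(cfg, "roror")), 9)
  dcf <- oat_sensitivity(cfg, "dcf")
  # restrictions on prevalent and incident pools move as one grouped bar
  expect_true("prescription_restrictions" %in% dcf$parameter)
  expect_false(any(c("restriction_prevalent", "restriction_incident") %in%
                     dcf$parameter))
  expect_equal(nrow(dcf), 15)
})

test_that("OAT base price is the average-scenario price and identity holds", {
  cfg <- lumasiran_config()
  for (m in c("ncp", "aim", "dcf", "roror")) {
    oat <- oat_sensitivity(cfg, m)
    avg_price <- glance(run_scenarios(cfg, m)) |>
      dplyr::filter(scenario == "avg") |>
      dplyr::pull(price_ppppy)
    expect_equal(unique(oat$base_price), avg_price)
    # a parameter whose columns agree spans a zero-width bar at the base
    flat <- dplyr::filter(oat, width == 0)
    if (nrow(flat) > 0) {
      expect_equal(flat$price_at_param_min, flat$base_price)
      expect_equal(flat$price_at_param_max, flat$base_price)
    }
  }
  # fixture sanity: COGS and marketing are identical across NCP columns
  ncp <- oat_sensitivity(cfg, "ncp")
  expect_equal(ncp$width[ncp$parameter == "cogs_ppppy"], 0)
})

test_that("prevalence spans the widest NCP tornado bar", {
  cfg <- lumasiran_config()
  ncp <- oat_sensitivity(cfg, "ncp")
  expect_equal(ncp$parameter[which.max(ncp$width)], "prevalence_per_million")
})

test_that("fixed-population analysis pins patients and ignores uptake", {
  cfg <- lumasiran_config()
  fp <- fixed_population_analysis(cfg, "ncp", n_patients = 1000)
  expect_equal(fp$min$price_ppppy,
               (830e6 * 0.3585 / (1000 * 14) + 38000 * 1.3) * 1.2)
  expect_equal(fp$min$intermediates$eligible_patients, 1000)

  # invariant to treatment rate / market share / uptake settings
  cfg2 <- cfg
  cfg2$models$ncp$min$treatment_rate <- 0.11
  cfg2$models$aim$max$market_share <- 0.9
  cfg2$models$dcf$min$uptake_cap <- 0.2
  cfg2$models$dcf$min$uptake_ramp_years <- 9
  for (m in c("ncp", "aim", "dcf")) {
    expect_equal(tidy(fixed_population_analysis(cfg2, m))$price_ppppy,
                 tidy(fixed_population_analysis(cfg, m))$price_ppppy)
  }
})

test_that("pinning the model's own patient count reproduces the scenario", {
  cfg <- lumasiran_config()
  cfg$models$ncp$min$treatment_rate <- 1
  own <- ncp_price(cfg$models$ncp$min, cfg$constants)
  pinned <- fixed_population_analysis(
    cfg, "ncp", n_patients = own$intermediates$eligible_patients)
  expect_equal(pinned$min$price_ppppy, own$price_ppppy)
})

test_that("a back-loading uptake ramp makes the pinned DCF price cheaper", {
  cfg <- lumasiran_config()
  inp <- cfg$models$dcf$min # ramp 6 back-loads patients
  own <- dcf_price(inp, cfg$constants)
  sched <- dcf_patient_schedule(inp, cfg$constants$eu_population)
  pinned <- dcf_price(inp, cfg$constants, n_patients = mean(sched$treated))
  expect_lte(pinned$price_ppppy, own$price_ppppy)
})

test_that("range overlap is the intersection of reported ranges", {
  fake <- function(lo, hi) {
    structure(list(model = "x",
                   results = list(min = list(reported_price = lo),
                                  max = list(reported_price = hi))),
              class = "scenario_set")
  }
  out <- range_overlap(list(fake(1, 5), fake(3, 9)))
  expect_equal(c(out$lower, out$upper), c(3, 5))
  expect_true(out$overlaps)
  expect_false(range_overlap(list(fake(1, 2), fake(5, 9)))$overlaps)

  cfg <- lumasiran_config()
  sets <- run_all_scenarios(cfg)
  ov <- range_overlap(sets)
  expect_equal(ov$lower, sets$dcf$results$min$reported_price)
  expect_equal(ov$upper, sets$ncp$results$max$reported_price)
  expect_true(ov$overlaps)
})
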