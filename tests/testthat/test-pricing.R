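# Component breakdowns must always sum to the price; model-specific
# compositions are checked against directly computed arithmetic oracles and
# the published reported prices.

breakdown_conserved <- function(res) {
  abs(sum(res$components) - res$price_ppppy) <=
    1e-9 * max(1, abs(res$price_ppppy))
}

test_that("R&D amortisation matches direct arithmetic and table rows", {
  expect_equal(rd_cost_ppppy(830e6, 0.3585, 907, 14), 830e6 * 0.3585 / (907 * 14))
  expect_equal(round_half_up(rd_cost_ppppy(830e6, 0.3585, 907, 14), 1000),
               23000) # printed ~EUR 23k
  expect_equal(rd_cost_ppppy(0, 0.3585, 907, 14), 0)
  expect_equal(round_half_up(rd_cost_ppppy(970e6, 0.3585, 604, 12), 1000),
               48000) # printed ~EUR 48k
  expect_error(rd_cost_ppppy(1e9, 0.3585, 0, 14),
               class = "omppricer_zero_patients")
  expect_error(rd_cost_ppppy(1e9, 0.3585, 907, 0),
               class = "omppricer_zero_years")
})

test_that("NCP composition reproduces the published price range", {
  cfg <- lumasiran_config()
  res_min <- ncp_price(cfg$models$ncp$min, cfg$constants)
  expect_equal(res_min$price_ppppy,
               (830e6 * 0.3585 / (907 * 14) + 38000 * 1.3) * 1.2)
  expect_equal(res_min$reported_price, 87000)
  expect_true(breakdown_conserved(res_min))
  expect_equal(res_min$intermediates$eligible_patients, 907)

  # published max/avg compose exactly from the printed intermediate rows
  expect_equal(report_price(ncp_compose(111000, 49000, 0.40)$price_ppppy),
               224000)
  expect_equal(report_price(ncp_compose(48000, 49000, 0.30)$price_ppppy),
               126000)

  # with no R&D and no margin the price is just the drug cost
  inp <- cfg$models$ncp$min
  inp$rd_cost_total <- 0
  inp$profit_margin <- 0
  expect_equal(ncp_price(inp, cfg$constants)$price_ppppy, 38000 * 1.3)
})

test_that("AIM composition hits EUR 33k under both bonus conventions", {
  cfg <- lumasiran_config()
  rd <- 800e6 * 0.3585 / (907 * 14)
  base <- rd + 3000 + 0.15 * rd

  res_add <- aim_price(cfg$models$aim$min, cfg$constants)
  expect_equal(res_add$price_ppppy, base * (1 + 0.08 + 0.05))
  expect_equal(res_add$reported_price, 33000)

  inp_mult <- cfg$models$aim$min
  inp_mult$bonus_convention <- "multiplicative"
  res_mult <- aim_price(inp_mult, cfg$constants)
  expect_equal(res_mult$price_ppppy, base * 1.08 * 1.05)
  expect_equal(res_mult$reported_price, 33000)
  expect_true(breakdown_conserved(res_mult))

  # average scenario, additive convention, against direct arithmetic
  avg <- build_average_inputs(cfg$models$aim$min, cfg$models$aim$max)
  rd_avg <- 950e6 * 0.3585 / (453 * 12)
  expect_equal(aim_price(avg, cfg$constants)$price_ppppy,
               (rd_avg * 1.175 + 6000) * (1 + 0.08 + 0.225))

  # no profit, no bonus: price equals the cost base
  inp <- cfg$models$aim$min
  inp$basic_profit <- 0
  inp$innovation_bonus <- 0
  expect_equal(aim_price(inp, cfg$constants)$price_ppppy, base)
})

test_that("npv follows the end-of-year convention", {
  expect_equal(npv(c(-100, 110), 0.10), 0)
  expect_equal(npv(c(5, -3, 7), 0), 9)
  expect_equal(npv(c(-100, 0, 121), 0.10), 0)
  expect_error(npv(c(1, 1), -1), class = "omppricer_out_of_range")
})

test_that("DCF break-even zeroes the NPV and matches a bisection root", {
  cfg <- lumasiran_config()
  for (seed in 1:40) {
    inp <- sample_inputs("dcf", seed)
    sched <- dcf_patient_schedule(inp, cfg$constants$eu_population)
    if (sum(sched$treated) < 1e-9) next
    p_star <- dcf_break_even_price(inp, cfg$constants)
    K <- inp$rd_lumpsum_total * cfg$constants$eu_attribution_share
    flows_at <- function(p) c(-K, p * sched$treated *
                                (1 - inp$drug_cost_fraction_of_revenue))
    expect_lt(abs(npv(flows_at(p_star), inp$cost_of_capital)) / K, 1e-6)
    # independent oracle: bisection on the NPV as a function of price
    root <- uniroot(function(p) npv(flows_at(p), inp$cost_of_capital),
                    interval = c(1e-6, 1e12), tol = 1e-8 * p_star)$root
    expect_equal(p_star, root, tolerance = 1e-6)
  }
})

test_that("DCF closed form collapses to simple amortisation at r = 0", {
  cfg <- lumasiran_config()
  inp <- cfg$models$dcf$min
  inp$cost_of_capital <- 0
  inp$innovation_premium <- 0
  inp$drug_cost_fraction_of_revenue <- 0
  # pinned constant schedule: P* = K / (n * T)
  res <- dcf_price(inp, cfg$constants, n_patients = 500)
  K <- 637e6 * 0.3585
  expect_equal(res$price_ppppy, K / (500 * 14))
  expect_equal(res$price_ppppy, rd_cost_ppppy(637e6, 0.3585, 500, 14))
  expect_equal(unname(res$components["cost_of_capital"]), 0)
})

test_that("the innovation premium scales the break-even price by 1 + eta", {
  cfg <- lumasiran_config()
  inp <- cfg$models$dcf$min
  p_star <- dcf_break_even_price(inp, cfg$constants)
  res <- dcf_price(inp, cfg$constants)
  expect_equal(res$price_ppppy, p_star * 1.05)
  expect_true(breakdown_conserved(res))
})

test_that("a schedule with no revenue raises a named error", {
  cfg <- lumasiran_config()
  inp <- cfg$models$dcf$min
  inp$prevalence_per_million <- 0
  inp$incidence_per_million <- 0
  expect_error(dcf_break_even_price(inp, cfg$constants),
               class = "omppricer_no_revenue")
})

test_that("ROROR compounding degenerates to cost-plus when wacc = deflator", {
  cfg <- lumasiran_config()
  inp <- cfg$models$roror$min
  inp$wacc <- 0.05
  inp$gdp_deflator <- 0.05
  res <- roror_price(inp, cfg$constants)
  rd <- 830e6 * 0.3585 / (907 * 14)
  expect_equal(res$price_ppppy, (38000 + rd) * 1.05)
  expect_equal(unname(res$components["cost_of_capital"]), 0)
  # independent of the development time when the ratio factor is 1
  inp$years_until_approval <- 12
  expect_equal(roror_price(inp, cfg$constants)$price_ppppy, res$price_ppppy)
  # and identical to the NCP composition with zero marketing surcharge
  ncp_inp <- cfg$models$ncp$min
  ncp_inp$marketing_fraction <- 0
  ncp_inp$profit_margin <- 0.05
  expect_equal(ncp_price(ncp_inp, cfg$constants)$price_ppppy, res$price_ppppy)
})

test_that("ROROR price strictly increases with the WACC", {
  cfg <- lumasiran_config()
  for (seed in 1:40) {
    inp <- sample_inputs("roror", seed)
    inp$years_until_approval <- max(1, inp$years_until_approval)
    lo <- roror_price(inp, cfg$constants)$price_ppppy
    inp2 <- inp
    inp2$wacc <- inp$wacc + 0.02
    expect_gt(roror_price(inp2, cfg$constants)$price_ppppy, lo)
  }
})

test_that("prices are finite, positive, and breakdowns conserved on draws", {
  cfg <- lumasiran_config()
  for (seed in 1:30) {
    for (m in c("ncp", "aim", "dcf", "roror")) {
      inp <- sample_inputs(m, seed)
      res <- switch(m,
                    ncp = ncp_price(inp, cfg$constants),
                    aim = aim_price(inp, cfg$constants),
                    dcf = dcf_price(inp, cfg$constants),
                    roror = roror_price(inp, cfg$constants))
      expect_true(is.finite(res$price_ppppy))
      expect_gt(res$price_ppppy, 0)
      expect_true(breakdown_conserved(res))
      expect_equal(res$reported_price %% cfg$constants$reporting_rounding, 0)
    }
  }
})
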