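test_that("median conversion recovers the median of the geometric process", {
  # one-cycle median is the definition of a median
  expect_equal(median_to_cycle_prob(1), 0.5)
  # closed form at the on-SSA progression median
  expect_equal(median_to_cycle_prob(14), 1 - 0.5^(1 / 14))
  expect_equal(median_to_cycle_prob(14), 0.04830, tolerance = 1e-3)
  # long medians give vanishing per-cycle probabilities
  expect_lt(median_to_cycle_prob(1e9), 1e-9)
  # brute-force CDF first passage: the smallest t with 1-(1-p)^t >= 0.5
  # equals the stated median, for every base-case median
  for (m in c(6, 14, 18, 39)) {
    p <- median_to_cycle_prob(m)
    cdf <- 1 - (1 - p)^(1:200)
    # the CDF hits exactly 0.5 at the median cycle; allow rounding slack
    expect_equal(which(cdf >= 0.5 - 1e-12)[1], m)
  }
  expect_error(median_to_cycle_prob(0), "> 0")
})

test_that("interval probabilities spread over cycles and compound back", {
  expect_equal(interval_prob_to_cycle_prob(0, 7), 0)
  expect_equal(interval_prob_to_cycle_prob(0.3, 1), 0.3)
  int_m <- 96 * 12 / 52  # 96 weeks in months
  p <- interval_prob_to_cycle_prob(0.01, int_m)
  expect_equal(p, 4.536e-4, tolerance = 1e-3)
  expect_equal(1 - (1 - p)^int_m, 0.01, tolerance = 1e-12)
  expect_error(interval_prob_to_cycle_prob(1, 5), "\\[0, 1\\)")
})

test_that("parameter sets validate and reject unknowns", {
  p <- gepnet_parameters()
  expect_s3_class(p, "gepnet_params")
  expect_equal(p$cost_ssa_month, 4121)
  expect_equal(p$median_progression_on_ssa, 14)
  expect_equal(gepnet_parameters(cost_ssa_month = 99)$cost_ssa_month, 99)
  expect_error(gepnet_parameters(not_a_param = 1), "unknown parameter")
  expect_error(gepnet_parameters(u_progressed = 1.3), "utilities")
  expect_error(gepnet_parameters(median_progression_on_ssa = -2), "medians")
  expect_error(gepnet_parameters(sa_ranges = list(cost_ssa_month = c(5000, 9000))),
               "bracket")
  # every default sensitivity range brackets its base value
  for (nm in names(p$sa_ranges)) {
    r <- p$sa_ranges[[nm]]
    expect_true(r[1] <= p[[nm]] && p[[nm]] <= r[2], label = nm)
  }
})

test_that("strategy arms start in the right state and conserve the cohort", {
  p <- gepnet_parameters()
  lt <- default_life_table()
  for (combine in c("sequential", "rate")) {
    m_ssa <- build_strategy(p, "SSA", lt, combine = combine)
    m_delay <- build_strategy(p, "DELAY", lt, combine = combine)
    expect_identical(m_ssa$initial_state, "StableOnSSA")
    expect_identical(m_delay$initial_state, "StableUntreated")
    expect_identical(m_ssa$states, m_delay$states)
    expect_rows_sum_to_one(run_cohort(m_ssa))
    expect_rows_sum_to_one(run_cohort(m_delay))
  }
  expect_error(build_strategy(p, "NOW", lt), "label")
})

test_that("model structure encodes the intended care pathway", {
  p <- gepnet_parameters()
  lt <- default_life_table()
  m <- build_strategy(p, "SSA", lt)
  P1 <- m$transitions[1, , ]
  # complications exit only from SSA-treated pre-PRRT states
  expect_gt(P1["StableOnSSA", "OffSSAComplication"], 0)
  expect_gt(P1["ProgressedOnSSA", "PRRT1_noSSA"], 0)  # straight to PRRT
  expect_equal(P1["StableUntreated", "OffSSAComplication"], 0)
  # the PRRT tunnel advances one state per cycle and then stays post-PRRT
  expect_gt(P1["PRRT1", "PRRT2"], 0.9)
  expect_equal(P1["PRRT1", "PRRT1"], 0)
  expect_gt(P1["PRRT4", "PostPRRT"], 0.9)
  expect_gt(P1["PostPRRT", "PostPRRT"], 0.9)
  # no SSA drug cost on the no-SSA chain; triple-dose SSA with PRRT
  expect_equal(unname(m$cost["PRRT1_noSSA"]), p$cost_prrt_cycle)
  expect_equal(unname(m$cost["PRRT1"]),
               p$cost_prrt_cycle + p$ssa_dose_mult_prrt * p$cost_ssa_month)
  expect_equal(unname(m$cost["PostPRRT_noSSA"]), 0)
  # utility mapping: uncontrolled symptoms only after complications
  expect_equal(unname(m$utility["OffSSAComplication"]), p$u_uncontrolled)
  expect_equal(unname(m$utility["ProgressedOnSSA"]), p$u_progressed)
})

test_that("with the disease switched off both arms reduce to background mortality", {
  p <- disease_off_params()
  lt <- default_life_table()
  ssa <- run_strategy(p, "SSA", lt)
  delay <- run_strategy(p, "DELAY", lt)
  expect_equal(ssa$ly, delay$ly, tolerance = 1e-12)
  # and both reproduce the life-table expectancy within discretization error
  expect_lt(abs(ssa$ly - life_expectancy(lt, 60)), 0.02)
})

test_that("NET-death attribution splits the two causes of death", {
  p <- gepnet_parameters()
  # background mortality disabled over the whole horizon: every death is a
  # NET death (the table closes far beyond the model's last age)
  lt_none <- life_table(60:150, c(rep(0, 90), 1))
  tr <- run_cohort(build_strategy(p, "SSA", lt_none))
  expect_equal(net_death_fraction(tr), 100)
  # disease disabled (vanishing hazards): essentially no NET deaths
  tr0 <- run_cohort(build_strategy(disease_off_params(), "SSA",
                                   default_life_table()))
  expect_lt(net_death_fraction(tr0), 1e-3)
})

test_that("immediate SSA buys survival and QALYs at higher cost", {
  p <- gepnet_parameters()
  lt <- default_life_table()
  ssa <- run_strategy(p, "SSA", lt)
  delay <- run_strategy(p, "DELAY", lt)
  expect_gt(ssa$ly, delay$ly)
  expect_gt(ssa$qaly, delay$qaly)
  expect_gt(ssa$cost, delay$cost)
  expect_lt(ssa$qaly, ssa$ly)
  expect_lt(delay$qaly, delay$ly)
})

test_that("strategy models pass the microsimulation cross-check", {
  p <- gepnet_parameters()
  lt <- default_life_table()
  m <- build_strategy(p, "DELAY", lt)
  tr <- run_cohort(m)
  exact <- accumulate_rewards(tr, m, annual_rate = p$discount_annual)
  sim <- microsim_oracle(m, n_individuals = 2e4, seed = 41,
                         annual_rate = p$discount_annual)
  expect_lt(abs(sim$total_ly - exact$total_ly), 3 * sim$se_ly)
  expect_lt(abs(sim$total_qaly - exact$total_qaly), 3 * sim$se_qaly)
  expect_lt(abs(sim$total_cost - exact$total_cost), 3 * sim$se_cost)
})
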