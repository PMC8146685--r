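test_that("competing-risk rate apportionment matches its closed forms", {
  # single event passes through unchanged
  expect_equal(combine_competing_risks(c(A = 0.1)), c(A = 0.1))
  # null events stay null and do not perturb the others
  expect_equal(combine_competing_risks(c(A = 0, B = 0.3)), c(A = 0, B = 0.3))
  # symmetric pair: total exit 1 - 0.8^2 = 0.36, shared equally
  expect_equal(combine_competing_risks(c(A = 0.2, B = 0.2)),
               c(A = 0.18, B = 0.18))
  # empty map -> empty map
  expect_length(combine_competing_risks(numeric(0)), 0)
  # adjusted probabilities always sum to 1 - prod(1 - p) <= 1
  set.seed(11)
  for (i in 1:20) {
    p <- stats::runif(3, 0, 0.9)
    adj <- combine_competing_risks(p)
    expect_equal(sum(adj), 1 - prod(1 - p), tolerance = 1e-12)
  }
  expect_error(combine_competing_risks(c(A = 1, B = 0.2)), "certain event")
  expect_error(combine_competing_risks(c(A = -0.1)), "\\[0, 1\\]")
})

test_that("rate apportionment agrees with an exponential-time simulation", {
  # independent oracle: draw exponential event times, record which event
  # fires first within one cycle
  p <- c(A = 0.2, B = 0.35)
  r <- -log(1 - p)
  set.seed(99)
  n <- 2e5
  tA <- stats::rexp(n, r["A"]); tB <- stats::rexp(n, r["B"])
  sim <- c(A = mean(tA < tB & tA < 1), B = mean(tB <= tA & tB < 1))
  adj <- combine_competing_risks(p)
  se <- sqrt(adj * (1 - adj) / n)
  expect_true(all(abs(adj - sim) < 3 * se))
})

test_that("sequential conditioning multiplies through earlier survivals", {
  p <- c(A = 0.3, B = 0.2, C = 0.1)
  adj <- combine_competing_risks(p, method = "sequential")
  expect_equal(unname(adj), c(0.3, 0.7 * 0.2, 0.7 * 0.8 * 0.1))
  expect_equal(sum(adj), 1 - prod(1 - p), tolerance = 1e-12)
})

test_that("cohort propagation is conservative and matches geometric decay", {
  m <- geometric_model(0.5)
  tr <- run_cohort(m, n_cycles = 30)
  expect_rows_sum_to_one(tr)
  expect_equal(tr[, "alive"], 0.5^(0:30))
  # absorbing occupancy never decreases
  expect_true(all(diff(tr[, "dead"]) >= 0))

  # a cohort parked in an absorbing state never moves
  m2 <- markov_model(c("a", "dead"), matrix(c(1, 0, 0, 1), 2, 2),
                     cost = c(a = 5, dead = 0), utility = c(a = 1, dead = 0),
                     absorbing = "dead", initial_state = "dead")
  tr2 <- run_cohort(m2, n_cycles = 10)
  expect_true(all(tr2[, "dead"] == 1))
})

test_that("models violating probability constraints are rejected", {
  expect_error(
    markov_model(c("a", "b"), matrix(c(0, 1.4, 0, 1), 2, 2, byrow = TRUE),
                 cost = c(a = 0, b = 0), utility = c(a = 1, b = 0),
                 absorbing = "b", initial_state = "a"),
    "\\[0, 1\\]")
  expect_error(
    markov_model(c("a", "b", "c"),
                 matrix(c(0, 0.6, 0.7, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
                 cost = c(a = 0, b = 0, c = 0),
                 utility = c(a = 1, b = 0, c = 0),
                 absorbing = c("b", "c"), initial_state = "a"),
    "sum to more than 1")
  # absorbing states must carry no rewards and no exits
  expect_error(
    markov_model(c("a", "b"), matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE),
                 cost = c(a = 0, b = 100), utility = c(a = 1, b = 0),
                 absorbing = "b", initial_state = "a"),
    "zero rewards")
})

test_that("discount factors follow (1+r)^(-t/12)", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(0:100, 0), rep(1, 101))
  expect_equal(discount_factor(30, 0.03), 1.03^(-30 / 12))
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("reward accumulation reproduces closed-form totals", {
  # immortal cohort, utility 1, no discounting: one year lived = 1 QALY = 1 LY
  m <- markov_model(c("alive", "dead"), matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                    cost = c(alive = 10, dead = 0),
                    utility = c(alive = 1, dead = 0),
                    absorbing = "dead", initial_state = "alive")
  tr <- run_cohort(m, n_cycles = 12)
  rw <- accumulate_rewards(tr, m, annual_rate = 0)
  expect_equal(rw$total_qaly, 1)
  expect_equal(rw$total_ly, 1)
  expect_equal(rw$total_cost, 120)

  # all-dead cohort accrues nothing
  m0 <- markov_model(c("alive", "dead"), matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                     cost = c(alive = 10, dead = 0),
                     utility = c(alive = 1, dead = 0),
                     absorbing = "dead", initial_state = "dead")
  rw0 <- accumulate_rewards(run_cohort(m0, 12), m0, annual_rate = 0)
  expect_equal(unlist(rw0), c(total_cost = 0, total_qaly = 0, total_ly = 0))

  # geometric decay p = 0.5: LY = (1/12) * sum_t (0.5^t + 0.5^(t+1))/2 = 0.125
  mg <- geometric_model(0.5)
  trg <- run_cohort(mg, n_cycles = 80)
  rwg <- accumulate_rewards(trg, mg, annual_rate = 0)
  brute <- sum((0.5^(0:79) + 0.5^(1:80)) / 2) / 12
  expect_equal(rwg$total_ly, brute)
  expect_equal(rwg$total_ly, 0.125, tolerance = 1e-12)
  # with utility 1 and no discount, QALYs equal LYs
  expect_equal(rwg$total_qaly, rwg$total_ly)
})

test_that("totals never increase with the discount rate", {
  m <- geometric_model(0.1, cost_alive = 100, utility_alive = 0.8)
  tr <- run_cohort(m, n_cycles = 120)
  rates <- c(0, 0.01, 0.03, 0.06, 0.1)
  costs <- vapply(rates, function(r) accumulate_rewards(tr, m, r)$total_cost,
                  numeric(1))
  qalys <- vapply(rates, function(r) accumulate_rewards(tr, m, r)$total_qaly,
                  numeric(1))
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
  # QALYs cannot exceed LYs
  expect_true(all(qalys <= accumulate_rewards(tr, m, 0)$total_ly))
})

test_that("microsimulation agrees with the cohort expectation", {
  mg <- geometric_model(0.5, cost_alive = 50)
  trg <- run_cohort(mg, n_cycles = 60)
  exact <- accumulate_rewards(trg, mg, annual_rate = 0.03)
  sim <- microsim_oracle(mg, n_individuals = 1e4, seed = 123,
                         annual_rate = 0.03, n_cycles = 60)
  expect_lt(abs(sim$total_ly - exact$total_ly), 3 * sim$se_ly)
  expect_lt(abs(sim$total_qaly - exact$total_qaly), 3 * sim$se_qaly)
  expect_lt(abs(sim$total_cost - exact$total_cost), 3 * sim$se_cost)

  # determinism: the same seed reproduces the estimate exactly
  sim2 <- microsim_oracle(mg, n_individuals = 500, seed = 7, n_cycles = 30)
  sim3 <- microsim_oracle(mg, n_individuals = 500, seed = 7, n_cycles = 30)
  expect_identical(sim2, sim3)

  # an absorbed cohort yields exact zeros whatever the seed
  m0 <- markov_model(c("alive", "dead"), matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                     cost = c(alive = 10, dead = 0),
                     utility = c(alive = 1, dead = 0),
                     absorbing = "dead", initial_state = "dead")
  s0 <- microsim_oracle(m0, n_individuals = 100, seed = 1, n_cycles = 10)
  expect_equal(s0$total_cost, 0)
  expect_equal(s0$total_ly, 0)
})

test_that("trace export carries cycle and age columns", {
  lt <- flat_life_table(0.2, 50, 70)
  m <- background_only_model(lt, start_age = 60)
  tr <- run_cohort(m)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, tmp)
  back <- utils::read.csv(tmp)
  expect_identical(names(back), c("cycle", "age", "alive", "dead"))
  expect_equal(back$age[1], 60)
  expect_equal(back$age[13], 61)
  expect_equal(back$alive, unname(tr[, "alive"]))
})
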