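# shared fixtures, built in code

# two-state alive -> dead model with constant per-cycle death probability
geometric_model <- function(p_die = 0.5, cost_alive = 0, utility_alive = 1) {
  markov_model(
    states = c("alive", "dead"),
    transitions = matrix(c(1 - p_die, p_die, 0, 1), 2, 2, byrow = TRUE),
    cost = c(alive = cost_alive, dead = 0),
    utility = c(alive = utility_alive, dead = 0),
    absorbing = "dead", initial_state = "alive")
}

# model whose only exit is life-table background mortality from `start_age`
background_only_model <- function(lt, start_age = 60, cycles_per_year = 12L) {
  horizon <- max(lt$age) + 1L
  n_cycles <- (horizon - start_age) * cycles_per_year
  ages <- floor(start_age + (seq_len(n_cycles) - 1L) / cycles_per_year)
  q <- lt$qx[match(pmin(ages, max(lt$age)), lt$age)]
  p <- annual_to_cycle_prob(q, cycles_per_year)
  P <- array(0, dim = c(n_cycles, 2, 2))
  P[, 1, 2] <- p
  P[, 1, 1] <- 1 - p
  P[, 2, 2] <- 1
  markov_model(states = c("alive", "dead"), transitions = P,
               cost = c(alive = 0, dead = 0),
               utility = c(alive = 1, dead = 0),
               absorbing = "dead", initial_state = "alive",
               start_age = start_age, cycles_per_year = cycles_per_year)
}

# a constant-hazard life table: q identical at all non-terminal ages
flat_life_table <- function(q, age_min = 0, age_max = 80) {
  ages <- age_min:age_max
  qx <- rep(q, length(ages))
  qx[length(qx)] <- 1
  life_table(ages, qx)
}

# parameter set with the disease switched off: no progression, no NET death,
# no complications -- only background mortality acts
disease_off_params <- function(...) {
  huge <- 1e9
  gepnet_parameters(
    median_net_death_untreated = huge, median_net_death_on_ssa = huge,
    median_net_death_on_prrt = huge, median_progression_off_ssa = huge,
    median_progression_on_ssa = huge, median_progression_delayed_ssa = huge,
    p_complication_interval = 0, ...)
}

# sa_ranges collapsed to zero width at the base values (degenerate PSA)
degenerate_ranges <- function(params) {
  r <- params$sa_ranges
  for (nm in names(r)) r[[nm]] <- rep(params[[nm]], 2)
  r
}

expect_rows_sum_to_one <- function(trace, tol = 1e-10) {
  expect_true(all(abs(rowSums(trace) - 1) < tol))
}
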