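#' Construct a Markov cohort model
#'
#' A time-inhomogeneous Markov cohort model over named health states, with a
#' per-cycle transition structure and per-state rewards. Transition
#' probabilities may vary by cycle (here only through age-indexed background
#' mortality); rewards are a cost per cycle occupied (dollars) and a utility
#' weight per year alive.
#'
#' @param states Character vector of state names (ordered).
#' @param transitions Either an \code{n_cycles x S x S} array of per-cycle
#'   transition probabilities, or a single \code{S x S} matrix reused every
#'   cycle. Each row's off-diagonal destinations must lie in \code{[0, 1]}
#'   and sum to at most 1; the remainder is added to the diagonal (stay).
#' @param cost Named numeric vector: cost in dollars accrued per cycle spent
#'   in each state.
#' @param utility Named numeric vector: utility weight (per year) of each
#'   state, in \code{[0, 1]} for alive states and 0 for dead states.
#' @param absorbing Character vector of absorbing (death) states. These must
#'   have no outgoing transitions and zero rewards.
#' @param initial_state Name of the state holding the whole cohort at cycle 0.
#' @param start_age Cohort age in years at cycle 0 (annotation only; used for
#'   the \code{age} column of exported traces).
#' @param cycles_per_year Model cycles per year; 12 (monthly) by default.
#'
#' @return An object of class \code{"markov_model"}.
#' @seealso [run_cohort()], [accumulate_rewards()], [microsim_oracle()]
#' @export
markov_model <- function(states, transitions, cost, utility, absorbing,
                         initial_state, start_age = NULL,
                         cycles_per_year = 12L) {
  states <- as.character(states)
  ns <- length(states)
  if (ns < 1L || anyDuplicated(states)) {
    stop("`states` must be non-empty and unique", call. = FALSE)
  }
  if (is.matrix(transitions)) {
    transitions <- array(transitions, dim = c(1L, ns, ns),
                         dimnames = list(NULL, states, states))
  }
  if (!is.array(transitions) || length(dim(transitions)) != 3L ||
      dim(transitions)[2L] != ns || dim(transitions)[3L] != ns) {
    stop("`transitions` must be an n_cycles x S x S array or an S x S matrix",
         call. = FALSE)
  }
  dimnames(transitions) <- list(NULL, states, states)
  if (anyNA(transitions)) {
    stop("transition probabilities must not be NA", call. = FALSE)
  }
  rng <- range(transitions)
  if (rng[1L] < -1e-12 || rng[2L] > 1 + 1e-12) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (rng[1L] < 0) transitions[transitions < 0] <- 0
  if (rng[2L] > 1) transitions[transitions > 1] <- 1
  # fold the stay probability into the diagonal (vectorised over cycles)
  nt <- dim(transitions)[1L]
  diag_idx <- cbind(rep(seq_len(nt), ns),
                    rep(seq_len(ns), each = nt),
                    rep(seq_len(ns), each = nt))
  dg <- matrix(transitions[diag_idx], nt, ns)
  exit <- rowSums(transitions, dims = 2L) - dg    # off-diagonal row sums [t, s]
  if (any(exit > 1 + 1e-9)) {
    bad <- which(exit > 1 + 1e-9, arr.ind = TRUE)[1L, ]
    stop("cycle ", bad[1L] - 1L, ": outgoing probabilities of state '",
         states[bad[2L]], "' sum to more than 1", call. = FALSE)
  }
  transitions[diag_idx] <- pmax(0, 1 - exit)
  cost <- cost[states]
  utility <- utility[states]
  if (anyNA(cost) || anyNA(utility)) {
    stop("`cost` and `utility` must be named for every state", call. = FALSE)
  }
  if (!all(absorbing %in% states)) stop("unknown absorbing state", call. = FALSE)
  if (!initial_state %in% states) stop("unknown `initial_state`", call. = FALSE)
  for (s in absorbing) {
    off <- transitions[, s, , drop = FALSE]
    off[, , s] <- 0
    if (any(off > 0)) stop("absorbing state '", s, "' has outgoing transitions",
                           call. = FALSE)
    if (cost[[s]] != 0 || utility[[s]] != 0) {
      stop("absorbing state '", s, "' must have zero rewards", call. = FALSE)
    }
  }
  structure(list(states = states, transitions = transitions, cost = cost,
                 utility = utility, absorbing = absorbing,
                 initial_state = initial_state, start_age = start_age,
                 cycles_per_year = as.integer(cycles_per_year)),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> %d states, %d cycle(s) of transitions, start '%s'\n",
              length(x$states), dim(x$transitions)[1L], x$initial_state))
  invisible(x)
}

#' Combine competing per-cycle exit probabilities
#'
#' Several exit events can compete for the same cycle. \code{method = "rate"}
#' converts each probability to a constant rate \eqn{r_i = -\log(1 - p_i)},
#' forms the total exit probability \eqn{P = 1 - e^{-\sum r_i}} and apportions
#' it as \eqn{P \, r_i / \sum r_j} (simultaneous exponential risks).
#' \code{method = "sequential"} conditions each event on all earlier events
#' in the supplied order not having fired,
#' \eqn{p_i \prod_{j<i} (1 - p_j)} (the chance-node ordering of a decision
#' tree). Both guarantee the adjusted probabilities sum to
#' \eqn{1 - \prod_i (1 - p_i) \le 1}.
#'
#' @param event_probs Named numeric vector of per-cycle probabilities in
#'   \code{[0, 1]}; at most one may equal 1, and only if all others are 0.
#' @param method \code{"rate"} (default) or \code{"sequential"}.
#' @return Named numeric vector of adjusted probabilities (same names/order).
#' @export
#' @examples
#' combine_competing_risks(c(A = 0.2, B = 0.2))  # c(A = 0.18, B = 0.18)
combine_competing_risks <- function(event_probs,
                                    method = c("rate", "sequential")) {
  method <- match.arg(method)
  p <- event_probs
  if (length(p) == 0L) return(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("event probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(p == 1) && sum(p > 0) > 1L) {
    stop("a certain event cannot compete with another event", call. = FALSE)
  }
  if (all(p == 0)) return(p)
  if (method == "rate") {
    if (any(p == 1)) return(p)  # single certain event passes through
    r <- -log1p(-p)
    total <- sum(r)
    out <- (1 - exp(-total)) * r / total
  } else {
    out <- p
    surv <- 1
    for (i in seq_along(p)) {
      out[i] <- surv * p[i]
      surv <- surv * (1 - p[i])
    }
  }
  out
}

#' Propagate a cohort through a Markov model
#'
#' Starts the whole cohort in \code{initial_state} and multiplies the
#' occupancy row through each cycle's transition matrix. If the model carries
#' fewer transition cycles than \code{n_cycles}, the last matrix is reused
#' (time-homogeneous tail).
#'
#' @param model A \code{markov_model}.
#' @param n_cycles Number of cycles to run; defaults to the number of
#'   transition cycles in the model.
#' @return A \code{"cohort_trace"}: an \code{(n_cycles + 1) x S} matrix of
#'   occupancy fractions (rows are cycles 0..n_cycles; each row sums to 1),
#'   with the model's state names as columns.
#' @export
run_cohort <- function(model, n_cycles = dim(model$transitions)[1L]) {
  stopifnot(inherits(model, "markov_model"))
  ns <- length(model$states)
  nt <- dim(model$transitions)[1L]
  v <- numeric(ns)
  names(v) <- model$states
  v[model$initial_state] <- 1
  trace <- matrix(0, n_cycles + 1L, ns, dimnames = list(NULL, model$states))
  trace[1L, ] <- v
  for (t in seq_len(n_cycles)) {
    P <- model$transitions[min(t, nt), , ]
    v <- as.numeric(v %*% P)
    trace[t + 1L, ] <- v
  }
  structure(trace, class = c("cohort_trace", class(trace)),
            absorbing = model$absorbing, start_age = model$start_age,
            cycles_per_year = model$cycles_per_year)
}

#' Discount factor for a model cycle
#'
#' \code{(1 + annual_rate)^(-cycle_index / cycles_per_year)}: discounting
#' compounds continuously in cycles at the stated annual rate. Cycle 0 is
#' undiscounted.
#'
#' @param cycle_index Cycle index (0-based); vectorised.
#' @param annual_rate Annual discount rate (>= 0), e.g. 0.03.
#' @param cycles_per_year Cycles per year (12 by default).
#' @return Discount factors in \code{(0, 1]}.
#' @export
discount_factor <- function(cycle_index, annual_rate, cycles_per_year = 12L) {
  if (any(annual_rate < 0)) stop("`annual_rate` must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle_index / cycles_per_year)
}

#' Accumulate costs, QALYs and life-years over a cohort trace
#'
#' Costs accrue on start-of-cycle occupancy (a month's drug is dispensed to
#' those entering the month) and are discounted. QALYs use a trapezoidal
#' half-cycle correction - the average of the occupancy at the two ends of
#' each cycle - weighted by \code{utility / cycles_per_year}, and are
#' discounted. Unadjusted life-years use the same trapezoid on the alive
#' fraction (1 minus occupancy of the absorbing death states) with no
#' discounting and no utility weighting.
#'
#' @param trace A \code{cohort_trace} from [run_cohort()].
#' @param model The \code{markov_model} that produced it.
#' @param annual_rate Annual discount rate applied to costs and QALYs.
#' @param hcc_costs Apply the half-cycle correction to costs as well
#'   (\code{FALSE} by default; see the package vignette).
#' @return A list of class \code{"reward_totals"} with elements
#'   \code{total_cost}, \code{total_qaly}, \code{total_ly}.
#' @export
accumulate_rewards <- function(trace, model, annual_rate = 0.03,
                               hcc_costs = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(model, "markov_model"))
  if (!identical(colnames(trace), model$states)) {
    stop("trace states do not match the model", call. = FALSE)
  }
  n <- nrow(trace) - 1L
  cpy <- model$cycles_per_year
  df <- discount_factor(0:(n - 1L), annual_rate, cpy)
  head_ <- trace[seq_len(n), , drop = FALSE]
  mid <- (head_ + trace[-1L, , drop = FALSE]) / 2
  occ_cost <- if (hcc_costs) mid else head_
  total_cost <- sum((occ_cost %*% model$cost) * df)
  total_qaly <- sum((mid %*% (model$utility / cpy)) * df)
  alive <- 1 - rowSums(trace[, model$absorbing, drop = FALSE])
  total_ly <- sum((alive[seq_len(n)] + alive[-1L]) / 2) / cpy
  structure(list(total_cost = total_cost, total_qaly = total_qaly,
                 total_ly = total_ly),
            class = "reward_totals")
}

#' @export
print.reward_totals <- function(x, ...) {
  cat(sprintf("<reward_totals> cost $%.0f | QALY %.3f | LY %.3f\n",
              x$total_cost, x$total_qaly, x$total_ly))
  invisible(x)
}

#' Individual-level microsimulation oracle
#'
#' Simulates \code{n_individuals} one cycle at a time with categorical draws
#' from the same per-cycle transition probabilities as [run_cohort()], and
#' accumulates the same rewards per individual (discounted costs, discounted
#' half-cycle-corrected QALYs, undiscounted life-years). The cohort trace is
#' the exact expectation of this process, so the two must agree within Monte
#' Carlo error; this is the engine's independent validation path, not an
#' alternative implementation of it.
#'
#' @param model A \code{markov_model}.
#' @param n_individuals Number of simulated individuals (>= 1).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param annual_rate Annual discount rate for costs and QALYs.
#' @param n_cycles Cycles to simulate (defaults to the model's).
#' @param hcc_costs As in [accumulate_rewards()].
#' @return A list with mean totals \code{total_cost}, \code{total_qaly},
#'   \code{total_ly} and their standard errors \code{se_cost},
#'   \code{se_qaly}, \code{se_ly}.
#' @export
microsim_oracle <- function(model, n_individuals, seed, annual_rate = 0.03,
                            n_cycles = dim(model$transitions)[1L],
                            hcc_costs = FALSE) {
  stopifnot(inherits(model, "markov_model"), n_individuals >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ns <- length(model$states)
  nt <- dim(model$transitions)[1L]
  cpy <- model$cycles_per_year
  df <- discount_factor(0:(n_cycles - 1L), annual_rate, cpy)
  is_dead <- model$states %in% model$absorbing
  state <- rep.int(match(model$initial_state, model$states), n_individuals)
  cost_acc <- qaly_acc <- ly_acc <- numeric(n_individuals)
  for (t in seq_len(n_cycles)) {
    P <- model$transitions[min(t, nt), , ]
    nxt <- state
    for (s in which(tabulate(state, ns) > 0L)) {
      idx <- which(state == s)
      if (!is_dead[s]) {
        nxt[idx] <- sample.int(ns, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
    u_mid <- (model$utility[state] + model$utility[nxt]) / 2
    alive_mid <- ((!is_dead[state]) + (!is_dead[nxt])) / 2
    occ_c <- if (hcc_costs) (model$cost[state] + model$cost[nxt]) / 2
             else model$cost[state]
    cost_acc <- cost_acc + occ_c * df[t]
    qaly_acc <- qaly_acc + (u_mid / cpy) * df[t]
    ly_acc <- ly_acc + alive_mid / cpy
    state <- nxt
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  list(total_cost = mean(cost_acc), total_qaly = mean(qaly_acc),
       total_ly = mean(ly_acc),
       se_cost = se(cost_acc), se_qaly = se(qaly_acc), se_ly = se(ly_acc),
       n = n_individuals)
}

#' Export a cohort trace to CSV
#'
#' One row per cycle, one column per state, plus \code{cycle} and \code{age}
#' columns (age advances by 1/cycles_per_year per cycle from the model's
#' start age).
#'
#' @param trace A \code{cohort_trace}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  cyc <- seq_len(nrow(trace)) - 1L
  cpy <- attr(trace, "cycles_per_year")
  age0 <- attr(trace, "start_age")
  age <- if (is.null(age0)) rep(NA_real_, length(cyc)) else age0 + cyc / cpy
  out <- data.frame(cycle = cyc, age = age, unclass(trace)[, , drop = FALSE],
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
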