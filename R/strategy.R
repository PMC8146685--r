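#' Convert a median time-to-event to a per-cycle probability
#'
#' Only medians are available for the disease transitions, so each is
#' interpreted as the median of an exponential time-to-event: the constant
#' per-cycle probability is \code{1 - 0.5^(1 / median_months)} for monthly
#' cycles. A process with this per-cycle probability has first-passage median
#' equal to \code{median_months} cycles.
#'
#' @param median_months Median time to the event in months (> 0); vectorised.
#' @return Per-cycle (monthly) probability of the event.
#' @export
#' @examples
#' median_to_cycle_prob(14)  # 0.0483...
median_to_cycle_prob <- function(median_months) {
  if (any(is.na(median_months)) || any(median_months <= 0)) {
    stop("`median_months` must be > 0", call. = FALSE)
  }
  1 - 0.5^(1 / median_months)
}

#' Convert an interval probability to a per-cycle probability
#'
#' A cumulative event probability observed over \code{interval_months} is
#' spread over monthly cycles under a constant hazard:
#' \code{1 - (1 - p_interval)^(1 / interval_months)}. Used for the SSA
#' serious-complication rate (about 1% over 96 weeks of exposure).
#'
#' @param p_interval Cumulative probability over the interval, in
#'   \code{[0, 1)}.
#' @param interval_months Interval length in months (> 0). Weeks convert as
#'   \code{weeks * 12 / 52}.
#' @return Per-cycle (monthly) probability.
#' @export
interval_prob_to_cycle_prob <- function(p_interval, interval_months) {
  if (any(is.na(p_interval)) || any(p_interval < 0) || any(p_interval >= 1)) {
    stop("`p_interval` must lie in [0, 1)", call. = FALSE)
  }
  if (any(interval_months <= 0)) {
    stop("`interval_months` must be > 0", call. = FALSE)
  }
  1 - (1 - p_interval)^(1 / interval_months)
}

#' Per-cycle model inputs derived from a parameter set
#'
#' Converts the clinical parameters (medians, interval probabilities) into
#' the per-cycle transition probabilities the model actually uses, and
#' carries the costs, utilities and settings along. The probabilistic
#' sensitivity analysis perturbs objects of this form directly, since its
#' beta distributions are placed on probabilities, not on medians.
#'
#' @param params A \code{gepnet_params} object.
#' @return A list of class \code{"gepnet_inputs"} with element \code{probs}
#'   (named per-cycle probabilities) plus costs, utilities and settings.
#' @export
model_inputs <- function(params) {
  stopifnot(inherits(params, "gepnet_params"))
  probs <- c(
    p_nd_untreated = median_to_cycle_prob(params$median_net_death_untreated),
    p_nd_on_ssa = median_to_cycle_prob(params$median_net_death_on_ssa),
    p_nd_on_prrt = median_to_cycle_prob(params$median_net_death_on_prrt),
    p_prog_off = median_to_cycle_prob(params$median_progression_off_ssa),
    p_prog_on = median_to_cycle_prob(params$median_progression_on_ssa),
    p_prog_delayed = median_to_cycle_prob(params$median_progression_delayed_ssa),
    p_complication = interval_prob_to_cycle_prob(
      params$p_complication_interval,
      params$complication_interval_weeks * 12 / 52)
  )
  structure(list(
    probs = probs,
    cost_ssa_month = params$cost_ssa_month,
    cost_prrt_cycle = params$cost_prrt_cycle,
    n_prrt_cycles = params$n_prrt_cycles,
    ssa_dose_mult_prrt = params$ssa_dose_mult_prrt,
    u_pre_ssa = params$u_pre_ssa,
    u_on_ssa = params$u_on_ssa,
    u_progressed = params$u_progressed,
    u_uncontrolled = params$u_uncontrolled,
    discount_annual = params$discount_annual,
    wtp = params$wtp,
    start_age = params$start_age,
    horizon_age = params$horizon_age,
    cycles_per_year = params$cycles_per_year
  ), class = "gepnet_inputs")
}

as_gepnet_inputs <- function(x) {
  if (inherits(x, "gepnet_inputs")) x
  else if (inherits(x, "gepnet_params")) model_inputs(x)
  else stop("expected a gepnet_params or gepnet_inputs object", call. = FALSE)
}

#' The two treatment strategies
#'
#' \code{"SSA"}: start somatostatin analogues immediately at diagnosis.
#' \code{"DELAY"}: observe, and start SSA at first disease progression.
#' @return Character vector of the two strategy labels.
#' @export
strategy_labels <- function() c("SSA", "DELAY")

# State names for a tunnel of k PRRT cycles. The parallel *_noSSA chain
# tracks patients who stopped SSA for a serious complication and therefore
# accrue no SSA drug cost during or after PRRT.
.gepnet_states <- function(k) {
  c("StableUntreated", "StableOnSSA", "OffSSAComplication", "ProgressedOnSSA",
    paste0("PRRT", seq_len(k)), "PostPRRT",
    paste0("PRRT", seq_len(k), "_noSSA"), "PostPRRT_noSSA",
    "DeadNET", "DeadOther")
}

#' Build the Markov model for one treatment strategy
#'
#' Assembles the full state-transition structure shared by both arms (only
#' the initial state differs): stable disease (untreated or on SSA), SSA
#' discontinued for complications, progressed on delayed SSA, a fixed-length
#' monthly PRRT tunnel with a parallel no-SSA-cost chain for patients whose
#' SSA was stopped for toxicity, post-PRRT follow-up, and two absorbing
#' death states (\code{DeadNET}, \code{DeadOther}). Competing exits from each
#' state - NET death, progression, complication, background death, in that
#' clinical order - are combined per \code{combine}; background mortality at
#' cycle t uses the life-table annual probability at age
#' \code{floor(start_age + t / cycles_per_year)} converted to a monthly
#' probability.
#'
#' @param x A \code{gepnet_params} or \code{gepnet_inputs} object.
#' @param label \code{"SSA"} (start treated) or \code{"DELAY"} (start
#'   untreated).
#' @param lt A \code{life_table} covering the cohort's ages.
#' @param combine How competing exits share a cycle: \code{"sequential"}
#'   (default; each exit conditioned on earlier exits not firing, the
#'   decision-tree convention) or \code{"rate"} (constant-rate apportionment,
#'   see [combine_competing_risks()]).
#' @return A \code{markov_model} spanning
#'   \code{(horizon_age - start_age + 1) * cycles_per_year} cycles (the
#'   cohort is followed through the horizon-age year).
#' @export
build_strategy <- function(x, label, lt,
                           combine = c("sequential", "rate")) {
  combine <- match.arg(combine)
  inp <- as_gepnet_inputs(x)
  if (!label %in% strategy_labels()) {
    stop("`label` must be one of ", paste(strategy_labels(), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(lt, "life_table"))
  if (inp$start_age < lt$age[1L]) {
    stop("life table does not cover the start age", call. = FALSE)
  }
  cpy <- inp$cycles_per_year
  # follow the cohort through the year of age `horizon_age` inclusive; with
  # the bundled table's terminal q = 1 at 100 this closes out the cohort
  n_cycles <- as.integer(round((inp$horizon_age - inp$start_age + 1) * cpy))
  k <- inp$n_prrt_cycles
  states <- .gepnet_states(k)
  ns <- length(states)
  pr <- inp$probs

  # background mortality per cycle, from the life table
  ages <- floor(inp$start_age + (seq_len(n_cycles) - 1L) / cpy)
  q_ann <- lt$qx[match(pmin(ages, max(lt$age)), lt$age)]
  if (anyNA(q_ann)) stop("life table does not cover ages ",
                         min(ages), "-", max(ages), call. = FALSE)
  bg <- annual_to_cycle_prob(q_ann, cpy)

  tun <- function(i, nossa = FALSE) {
    nm <- paste0("PRRT", i, if (nossa) "_noSSA" else "")
    if (i <= k) nm else paste0("PostPRRT", if (nossa) "_noSSA" else "")
  }
  # ordered competing exits per transient state: NET death, progression,
  # complication, then background death (appended below)
  exits <- list(
    StableUntreated = c(DeadNET = unname(pr["p_nd_untreated"]),
                        ProgressedOnSSA = unname(pr["p_prog_off"])),
    StableOnSSA = c(DeadNET = unname(pr["p_nd_on_ssa"]),
                    stats::setNames(unname(pr["p_prog_on"]), tun(1)),
                    OffSSAComplication = unname(pr["p_complication"])),
    OffSSAComplication = c(DeadNET = unname(pr["p_nd_untreated"]),
                           stats::setNames(unname(pr["p_prog_off"]), tun(1, TRUE))),
    ProgressedOnSSA = c(DeadNET = unname(pr["p_nd_on_ssa"]),
                        stats::setNames(unname(pr["p_prog_delayed"]), tun(1)),
                        stats::setNames(unname(pr["p_complication"]), tun(1, TRUE)))
  )
  advance <- character(0)
  for (i in seq_len(k)) {
    exits[[tun(i)]] <- c(DeadNET = unname(pr["p_nd_on_prrt"]))
    exits[[tun(i, TRUE)]] <- c(DeadNET = unname(pr["p_nd_on_prrt"]))
    advance[tun(i)] <- tun(i + 1L)
    advance[tun(i, TRUE)] <- tun(i + 1L, TRUE)
  }
  exits[["PostPRRT"]] <- c(DeadNET = unname(pr["p_nd_on_prrt"]))
  exits[["PostPRRT_noSSA"]] <- c(DeadNET = unname(pr["p_nd_on_prrt"]))

  P <- array(0, dim = c(n_cycles, ns, ns), dimnames = list(NULL, states, states))
  for (s in names(exits)) {
    p_const <- exits[[s]]
    if (combine == "sequential") {
      surv_prefix <- cumprod(c(1, 1 - p_const))
      share <- p_const * surv_prefix[seq_along(p_const)]
      surv_all <- surv_prefix[length(surv_prefix)]
      bg_share <- bg * surv_all          # background death drawn last
      stay <- surv_all * (1 - bg)
    } else {
      r_const <- -log1p(-p_const)
      r_bg <- -log1p(-bg)
      total <- sum(r_const) + r_bg       # vector over cycles
      p_exit <- 1 - exp(-total)
      share_mat <- outer(p_exit / total, r_const)  # n_cycles x n_exits
      bg_share <- p_exit * r_bg / total
      # a certain background death (q = 1, infinite rate) claims the cycle
      inf_bg <- !is.finite(r_bg)
      if (any(inf_bg)) {
        share_mat[inf_bg, ] <- 0
        bg_share[inf_bg] <- 1
      }
      stay <- 1 - p_exit
      share <- share_mat                 # matrix; handled below
    }
    for (j in seq_along(p_const)) {
      dest <- names(p_const)[j]
      P[, s, dest] <- P[, s, dest] +
        (if (is.matrix(share)) share[, j] else share[j])
    }
    P[, s, "DeadOther"] <- P[, s, "DeadOther"] + bg_share
    stay_dest <- if (s %in% names(advance)) advance[[s]] else s
    P[, s, stay_dest] <- P[, s, stay_dest] + stay
  }
  P[, "DeadNET", "DeadNET"] <- 1
  P[, "DeadOther", "DeadOther"] <- 1

  mult <- inp$ssa_dose_mult_prrt
  cost <- stats::setNames(numeric(ns), states)
  cost["StableOnSSA"] <- inp$cost_ssa_month
  cost["ProgressedOnSSA"] <- inp$cost_ssa_month
  cost[paste0("PRRT", seq_len(k))] <-
    inp$cost_prrt_cycle + mult * inp$cost_ssa_month
  cost["PostPRRT"] <- mult * inp$cost_ssa_month
  cost[paste0("PRRT", seq_len(k), "_noSSA")] <- inp$cost_prrt_cycle
  utility <- stats::setNames(rep(inp$u_progressed, ns), states)
  utility["StableUntreated"] <- inp$u_pre_ssa
  utility["StableOnSSA"] <- inp$u_on_ssa
  utility["OffSSAComplication"] <- inp$u_uncontrolled
  utility[c("DeadNET", "DeadOther")] <- 0

  markov_model(
    states = states, transitions = P, cost = cost, utility = utility,
    absorbing = c("DeadNET", "DeadOther"),
    initial_state = if (label == "SSA") "StableOnSSA" else "StableUntreated",
    start_age = inp$start_age, cycles_per_year = cpy)
}

#' Fraction of deaths attributable to GEP-NET
#'
#' At the final cycle of a trace, the percentage of all deaths that occurred
#' in \code{DeadNET} rather than \code{DeadOther}.
#'
#' @param trace A \code{cohort_trace} containing \code{DeadNET} and
#'   \code{DeadOther} columns.
#' @return Percentage in \code{[0, 100]}.
#' @export
net_death_fraction <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (!all(c("DeadNET", "DeadOther") %in% colnames(trace))) {
    stop("trace lacks DeadNET/DeadOther states", call. = FALSE)
  }
  fin <- trace[nrow(trace), ]
  tot <- fin[["DeadNET"]] + fin[["DeadOther"]]
  if (tot <= 0) stop("no deaths at the horizon; fraction undefined", call. = FALSE)
  100 * fin[["DeadNET"]] / tot
}

#' Run one strategy end to end
#'
#' Builds the strategy model, propagates the cohort to the horizon and
#' accumulates rewards: discounted cost, discounted half-cycle-corrected
#' QALYs, undiscounted life-years, and the NET-death percentage.
#'
#' @inheritParams build_strategy
#' @return A list of class \code{"strategy_outcome"} with elements
#'   \code{label}, \code{cost}, \code{ly}, \code{qaly}, \code{net_death_pct}.
#' @export
run_strategy <- function(x, label, lt, combine = "sequential") {
  inp <- as_gepnet_inputs(x)
  model <- build_strategy(inp, label, lt, combine = combine)
  trace <- run_cohort(model)
  rw <- accumulate_rewards(trace, model, annual_rate = inp$discount_annual)
  structure(list(label = label, cost = rw$total_cost, ly = rw$total_ly,
                 qaly = rw$total_qaly,
                 net_death_pct = net_death_fraction(trace)),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %-5s cost $%.0f | LY %.3f | QALY %.3f | NET deaths %.1f%%\n",
              x$label, x$cost, x$ly, x$qaly, x$net_death_pct))
  invisible(x)
}

#' Run the base-case comparison of both strategies
#'
#' Convenience wrapper: runs \code{"SSA"} and \code{"DELAY"} and compares
#' them at the parameter set's willingness-to-pay threshold.
#'
#' @inheritParams build_strategy
#' @return A \code{cea_result}; see [compare_strategies()].
#' @export
run_base_case <- function(x, lt = default_life_table(),
                          combine = "sequential") {
  inp <- as_gepnet_inputs(x)
  ssa <- run_strategy(inp, "SSA", lt, combine = combine)
  delay <- run_strategy(inp, "DELAY", lt, combine = combine)
  compare_strategies(ssa, delay, wtp = inp$wtp)
}
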