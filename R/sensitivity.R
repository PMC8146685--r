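# replace one parameter value, revalidating the set
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "gepnet_params"))
  if (!name %in% names(params)) stop("unknown parameter: ", name, call. = FALSE)
  params[[name]] <- value
  if (name %in% names(params$sa_ranges)) {
    r <- params$sa_ranges[[name]]
    params$sa_ranges[[name]] <- c(min(r[1L], value), max(r[2L], value))
  }
  validate_gepnet_params(params)
  params
}

icer_at <- function(params, lt, combine = "sequential") {
  inp <- model_inputs(params)
  s <- run_strategy(inp, "SSA", lt, combine = combine)
  d <- run_strategy(inp, "DELAY", lt, combine = combine)
  res <- compare_strategies(s, d, wtp = params$wtp)
  # report the ICER of SSA relative to DELAY: negative QALY increments
  # (SSA dominated or dominant in reverse) are flagged NA by compare
  res
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full two-strategy comparison with each parameter in
#' \code{params$sa_ranges} set to its low and to its high bound, all else at
#' base, and records both ICERs. Entries are sorted by bar width (absolute
#' ICER span) descending, the tornado-diagram convention. A bound producing
#' a non-positive QALY increment leaves that ICER \code{NA} with the
#' \code{dominance} flag set.
#'
#' @param params A \code{gepnet_params} with populated \code{sa_ranges}.
#' @param lt A \code{life_table}.
#' @param combine Competing-risk combination passed to [build_strategy()].
#' @return A \code{data.frame} of class \code{"tornado"} with columns
#'   \code{parameter}, \code{low_input}, \code{high_input}, \code{icer_low},
#'   \code{icer_high}, \code{width}, \code{dominance}; the base-case ICER is
#'   attached as attribute \code{"base_icer"}.
#' @export
one_way_dsa <- function(params, lt, combine = "sequential") {
  stopifnot(inherits(params, "gepnet_params"))
  base <- icer_at(params, lt, combine)
  nms <- names(params$sa_ranges)
  rows <- lapply(nms, function(nm) {
    r <- params$sa_ranges[[nm]]
    res_lo <- icer_at(set_param(params, nm, r[1L]), lt, combine)
    res_hi <- icer_at(set_param(params, nm, r[2L]), lt, combine)
    # ICERs are reported for SSA vs DELAY with sign information retained:
    # a dominant SSA (more QALYs, cheaper) keeps NA + flag
    ic <- function(res) if (res$more_effective == "SSA") res$icer else NA_real_
    flagged <- function(res) res$undefined || res$dominant ||
      res$more_effective != "SSA"
    data.frame(parameter = nm, low_input = r[1L], high_input = r[2L],
               icer_low = ic(res_lo), icer_high = ic(res_hi),
               dominance = flagged(res_lo) || flagged(res_hi))
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$width), c("parameter", "low_input", "high_input",
                                  "icer_low", "icer_high", "width",
                                  "dominance")]
  rownames(out) <- NULL
  structure(out, base_icer = base$icer, class = c("tornado", "data.frame"))
}

#' Threshold price analysis
#'
#' Root-finds the value of one cost parameter at which the SSA-vs-DELAY ICER
#' equals the willingness-to-pay threshold, by bisection over
#' \code{bracket} to a tolerance of $0.01 on the price. The ICER must be
#' monotone over the bracket (checked numerically at the ends and midpoint);
#' if the ICER minus WTP does not change sign across the bracket, an error
#' reports the ICER at both ends.
#'
#' @param params A \code{gepnet_params}.
#' @param lt A \code{life_table}.
#' @param wtp Willingness-to-pay threshold in $/QALY.
#' @param target Name of the parameter to solve for
#'   (default \code{"cost_ssa_month"}).
#' @param bracket Search interval; defaults to \code{c(0, base value)}.
#' @param combine Competing-risk combination passed to [build_strategy()].
#' @return The threshold value of \code{target}, in its own units.
#' @export
threshold_price <- function(params, lt, wtp = params$wtp,
                            target = "cost_ssa_month",
                            bracket = c(0, params[[target]]),
                            combine = "sequential") {
  stopifnot(inherits(params, "gepnet_params"))
  f <- function(x) {
    res <- icer_at(set_param(params, target, x), lt, combine)
    if (is.na(res$icer) || res$more_effective != "SSA") {
      stop("ICER undefined at ", target, " = ", x, call. = FALSE)
    }
    res$icer - wtp
  }
  f_lo <- f(bracket[1L]); f_hi <- f(bracket[2L]); f_mid <- f(mean(bracket))
  if (sign(f_mid - f_lo) * sign(f_hi - f_mid) < 0) {
    stop("ICER is not monotone over the bracket", call. = FALSE)
  }
  if (sign(f_lo) * sign(f_hi) > 0) {
    stop(sprintf("no threshold in [%g, %g]: ICER is %.0f and %.0f at the ends",
                 bracket[1L], bracket[2L], f_lo + wtp, f_hi + wtp),
         call. = FALSE)
  }
  stats::uniroot(f, bracket, tol = 0.01)$root
}

#' Gamma / beta parameters by the method of moments
#'
#' Helpers mapping a (mean, SD) pair onto gamma (shape, rate) or beta
#' (shape1, shape2) parameters. For the beta, an SD at or beyond the
#' feasibility bound \eqn{\sqrt{m(1-m)}} is shrunk to 0.99 of the bound.
#'
#' @param mean,sd Target mean and standard deviation (\code{mean} in
#'   \code{(0, 1)} for the beta).
#' @return Named numeric vector of distribution parameters.
#' @export
gamma_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  c(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' @rdname gamma_moments
#' @export
beta_moments <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  bound <- sqrt(mean * (1 - mean))
  if (sd >= bound) sd <- 0.99 * bound
  nu <- mean * (1 - mean) / sd^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# mean/sd pairs for every sampled quantity, in a fixed draw order.
# SDs equate each deterministic sensitivity range with a 95% interval
# (SD = range / 3.92); ranges on medians are first converted to per-cycle
# probabilities (the beta draws live on the probability scale).
psa_spec <- function(params) {
  r <- params$sa_ranges
  med_prob <- function(base_nm) {
    rr <- r[[base_nm]]
    p <- median_to_cycle_prob(params[[base_nm]])
    # note the inversion: a longer median means a smaller probability
    c(mean = p,
      sd = (median_to_cycle_prob(rr[1L]) - median_to_cycle_prob(rr[2L])) / 3.92)
  }
  int_m <- params$complication_interval_weeks * 12 / 52
  comp <- c(mean = interval_prob_to_cycle_prob(params$p_complication_interval, int_m),
            sd = (interval_prob_to_cycle_prob(r$p_complication_interval[2L], int_m) -
                  interval_prob_to_cycle_prob(r$p_complication_interval[1L], int_m)) / 3.92)
  util <- function(nm) c(mean = params[[nm]], sd = diff(r[[nm]]) / 3.92)
  list(
    gamma = list(
      cost_ssa_month = c(mean = params$cost_ssa_month,
                         sd = diff(r$cost_ssa_month) / 3.92),
      cost_prrt_cycle = c(mean = params$cost_prrt_cycle,
                          sd = diff(r$cost_prrt_cycle) / 3.92)),
    beta = list(
      u_pre_ssa = util("u_pre_ssa"), u_on_ssa = util("u_on_ssa"),
      u_progressed = util("u_progressed"),
      u_uncontrolled = util("u_uncontrolled"),
      p_nd_untreated = med_prob("median_net_death_untreated"),
      p_nd_on_ssa = med_prob("median_net_death_on_ssa"),
      p_nd_on_prrt = med_prob("median_net_death_on_prrt"),
      p_prog_off = med_prob("median_progression_off_ssa"),
      p_prog_on = med_prob("median_progression_on_ssa"),
      p_prog_delayed = med_prob("median_progression_delayed_ssa"),
      p_complication = comp))
}

#' Draw one probabilistic-sensitivity-analysis parameter sample
#'
#' Draws every cost from a gamma distribution and every utility and
#' per-cycle probability from a beta distribution, independently, with means
#' at the base-case values and standard deviations equating the
#' deterministic sensitivity ranges with 95% intervals
#' (\code{SD = range / 3.92}). Medians are converted to per-cycle
#' probabilities before sampling. Uses the current RNG state; seed it with
#' \code{set.seed()} (or use [run_psa()], which does).
#'
#' @param params A \code{gepnet_params}.
#' @return A \code{gepnet_inputs} object with sampled costs, utilities and
#'   probabilities (settings, dose multiplier and discount rate unchanged).
#' @export
draw_psa_sample <- function(params) {
  stopifnot(inherits(params, "gepnet_params"))
  spec <- psa_spec(params)
  inp <- model_inputs(params)
  for (nm in names(spec$gamma)) {
    ms <- spec$gamma[[nm]]
    inp[[nm]] <- if (ms["sd"] <= 0) ms[["mean"]] else {
      g <- gamma_moments(ms[["mean"]], ms[["sd"]])
      stats::rgamma(1L, shape = g[["shape"]], rate = g[["rate"]])
    }
  }
  for (nm in names(spec$beta)) {
    ms <- spec$beta[[nm]]
    val <- if (ms["sd"] <= 0) ms[["mean"]] else {
      b <- beta_moments(ms[["mean"]], ms[["sd"]])
      stats::rbeta(1L, shape1 = b[["shape1"]], shape2 = b[["shape2"]])
    }
    if (startsWith(nm, "u_")) inp[[nm]] <- val else inp$probs[[nm]] <- val
  }
  inp
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the parameter distributions of [draw_psa_sample()]: each
#' iteration draws a full sample, runs both strategies through the cohort
#' model, and records the incremental (SSA minus DELAY) discounted cost and
#' QALYs. Reproducible given \code{seed}.
#'
#' @param params A \code{gepnet_params}.
#' @param lt A \code{life_table}.
#' @param n_iterations Number of Monte Carlo iterations (>= 1).
#' @param seed Integer RNG seed (default 20211).
#' @param combine Competing-risk combination passed to [build_strategy()].
#' @return A \code{data.frame} of class \code{"psa_result"} with columns
#'   \code{iteration}, \code{delta_cost}, \code{delta_qaly}; the seed,
#'   iteration count and WTP are attached as attributes.
#' @export
run_psa <- function(params, lt, n_iterations = 1e5, seed = 20211,
                    combine = "sequential") {
  stopifnot(inherits(params, "gepnet_params"), n_iterations >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d_cost <- d_qaly <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    inp <- draw_psa_sample(params)
    s <- run_strategy(inp, "SSA", lt, combine = combine)
    d <- run_strategy(inp, "DELAY", lt, combine = combine)
    d_cost[i] <- s$cost - d$cost
    d_qaly[i] <- s$qaly - d$qaly
  }
  structure(data.frame(iteration = seq_len(n_iterations),
                       delta_cost = d_cost, delta_qaly = d_qaly),
            seed = seed, n_iterations = n_iterations, wtp = params$wtp,
            class = c("psa_result", "data.frame"))
}

#' Fraction of PSA iterations in which SSA is cost-effective
#'
#' At a willingness-to-pay \code{wtp}, the fraction of iterations whose
#' incremental net monetary benefit \code{wtp * delta_qaly - delta_cost} is
#' positive.
#'
#' @param psa A \code{psa_result}.
#' @param wtp Willingness-to-pay in $/QALY (scalar).
#' @return Fraction in \code{[0, 1]}.
#' @export
psa_ce_fraction <- function(psa, wtp) {
  stopifnot(inherits(psa, "psa_result"), length(wtp) == 1L)
  mean(wtp * psa$delta_qaly - psa$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' Evaluates [psa_ce_fraction()] over a grid of willingness-to-pay values.
#'
#' @param psa A \code{psa_result}.
#' @param wtp_grid Non-empty numeric vector of WTP values (>= 0).
#' @return A \code{data.frame} with columns \code{wtp} and
#'   \code{prob_cost_effective}.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0L) stop("`wtp_grid` must be non-empty", call. = FALSE)
  if (nrow(psa) == 0L) stop("empty PSA result", call. = FALSE)
  data.frame(wtp = wtp_grid,
             prob_cost_effective = vapply(wtp_grid, psa_ce_fraction,
                                          numeric(1L), psa = psa))
}
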