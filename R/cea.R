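#' Incremental cost-effectiveness comparison of two strategies
#'
#' Orders the two strategies by QALYs (ties broken by lower cost, i.e. weak
#' dominance) and computes the increments of the higher-QALY strategy over
#' the lower: incremental cost, life-years and QALYs, and the incremental
#' cost-effectiveness ratio (ICER) on the efficiency frontier. A strategy
#' with more QALYs at lower cost dominates: the ICER is undefined and the
#' strategy is cost-effective at any willingness-to-pay. Equal QALYs leave
#' the ICER undefined and flagged.
#'
#' @param x,y Two \code{strategy_outcome} objects with distinct labels.
#' @param wtp Willingness-to-pay threshold in $/QALY.
#' @return A list of class \code{"cea_result"}: \code{outcomes} (named list
#'   of both outcomes), \code{more_effective} (label), \code{incremental_cost},
#'   \code{incremental_ly}, \code{incremental_qaly}, \code{icer} (\code{NA}
#'   if dominant or undefined), \code{dominant}, \code{undefined},
#'   \code{cost_effective_at_wtp}, \code{wtp}.
#' @export
compare_strategies <- function(x, y, wtp = 1e5) {
  stopifnot(inherits(x, "strategy_outcome"), inherits(y, "strategy_outcome"))
  if (identical(x$label, y$label)) {
    stop("the two outcomes must belong to distinct strategies", call. = FALSE)
  }
  if (wtp < 0) stop("`wtp` must be >= 0", call. = FALSE)
  # frontier ordering: by QALY, ties by lower cost
  swap <- (y$qaly > x$qaly) || (y$qaly == x$qaly && y$cost < x$cost)
  strong <- if (swap) y else x
  weak <- if (swap) x else y
  d_cost <- strong$cost - weak$cost
  d_ly <- strong$ly - weak$ly
  d_qaly <- strong$qaly - weak$qaly
  undefined <- d_qaly == 0
  dominant <- !undefined && d_cost < 0
  icer <- if (undefined || dominant) NA_real_ else d_cost / d_qaly
  ce <- if (undefined) NA else dominant || icer <= wtp
  structure(list(
    outcomes = stats::setNames(list(strong, weak), c(strong$label, weak$label)),
    more_effective = strong$label,
    incremental_cost = d_cost, incremental_ly = d_ly,
    incremental_qaly = d_qaly, icer = icer,
    dominant = dominant, undefined = undefined,
    cost_effective_at_wtp = ce, wtp = wtp),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  for (o in x$outcomes) {
    cat(sprintf("  %-5s cost $%.0f | LY %.3f | QALY %.3f\n",
                o$label, o$cost, o$ly, o$qaly))
  }
  cat(sprintf("  incremental (%s vs %s): cost $%.0f | LY %.3f | QALY %.3f\n",
              names(x$outcomes)[1L], names(x$outcomes)[2L],
              x$incremental_cost, x$incremental_ly, x$incremental_qaly))
  if (x$undefined) {
    cat("  ICER undefined (equal QALYs)\n")
  } else if (x$dominant) {
    cat(sprintf("  %s dominates (more QALYs, lower cost)\n", x$more_effective))
  } else {
    cat(sprintf("  ICER $%.0f/QALY - %scost-effective at WTP $%.0f/QALY\n",
                x$icer, if (x$cost_effective_at_wtp) "" else "NOT ",
                x$wtp))
  }
  invisible(x)
}

#' Net monetary benefit of a strategy outcome
#'
#' \code{wtp * qaly - cost}. For two strategies with a positive QALY
#' increment, the sign of the NMB difference reproduces the ICER-vs-WTP
#' verdict.
#'
#' @param outcome A \code{strategy_outcome}.
#' @param wtp Willingness-to-pay threshold in $/QALY (>= 0).
#' @return NMB in dollars.
#' @export
nmb <- function(outcome, wtp) {
  stopifnot(inherits(outcome, "strategy_outcome"))
  if (any(wtp < 0)) stop("`wtp` must be >= 0", call. = FALSE)
  wtp * outcome$qaly - outcome$cost
}

#' Tabulate a CEA result like a results table
#'
#' One row per strategy (frontier order), with cost, incremental cost,
#' life-years, incremental LYs, QALYs, incremental QALYs, ICER and the
#' NET-death percentage.
#'
#' @param result A \code{cea_result}.
#' @return A \code{data.frame}.
#' @export
cea_table <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  s <- result$outcomes[[1L]]
  w <- result$outcomes[[2L]]
  data.frame(
    strategy = c(s$label, w$label),
    cost = c(s$cost, w$cost),
    incremental_cost = c(result$incremental_cost, NA),
    ly = c(s$ly, w$ly),
    incremental_ly = c(result$incremental_ly, NA),
    qaly = c(s$qaly, w$qaly),
    incremental_qaly = c(result$incremental_qaly, NA),
    icer = c(result$icer, NA),
    net_death_pct = c(s$net_death_pct, w$net_death_pct))
}

#' Serialise a CEA result to JSON
#'
#' @param result A \code{cea_result}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cea_json <- function(result, path) {
  stopifnot(inherits(result, "cea_result"))
  out <- list(
    outcomes = lapply(result$outcomes, function(o) {
      list(label = o$label, cost = o$cost, ly = o$ly, qaly = o$qaly,
           net_death_pct = o$net_death_pct)
    }),
    more_effective = result$more_effective,
    incremental_cost = result$incremental_cost,
    incremental_ly = result$incremental_ly,
    incremental_qaly = result$incremental_qaly,
    icer = result$icer, dominant = result$dominant,
    undefined = result$undefined,
    cost_effective_at_wtp = result$cost_effective_at_wtp,
    wtp = result$wtp)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
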