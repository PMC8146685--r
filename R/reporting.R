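#' Assemble a run configuration
#'
#' Bundles everything a reporting command needs: the effective parameter
#' set, the life-table source, the output directory, the RNG seed, the PSA
#' iteration count and the CEAC willingness-to-pay grid.
#'
#' @param params A \code{gepnet_params} (default: all base-case values).
#' @param life_table A \code{life_table}, a path to a life-table CSV, or
#'   \code{NULL} for the packaged table.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer RNG seed recorded in all outputs.
#' @param n_psa_iterations Monte Carlo iterations for [cmd_psa()].
#' @param wtp_grid WTP grid for the acceptability curve.
#' @param combine Competing-risk combination passed to [build_strategy()].
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(params = gepnet_parameters(), life_table = NULL,
                       out_dir = ".", seed = 20211L,
                       n_psa_iterations = 1e5,
                       wtp_grid = seq(0, 5e5, by = 1e4),
                       combine = "sequential") {
  stopifnot(inherits(params, "gepnet_params"))
  lt <- if (is.null(life_table)) default_life_table()
        else if (inherits(life_table, "life_table")) life_table
        else read_life_table(life_table)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  structure(list(params = params, lt = lt, out_dir = out_dir,
                 seed = as.integer(seed),
                 n_psa_iterations = n_psa_iterations, wtp_grid = wtp_grid,
                 combine = combine),
            class = "run_config")
}

# md5 of a canonical text serialization of the effective parameters
params_hash <- function(params) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  flat <- unlist(params[order(names(unclass(params)))])
  writeLines(paste(names(flat), format(flat, digits = 15), sep = "="), tf)
  unname(tools::md5sum(tf))
}

provenance_header <- function(config) {
  ver <- as.character(utils::packageVersion("gepnetcea"))
  sprintf("# gepnetcea %s | seed=%d | params_md5=%s",
          ver, config$seed, params_hash(config$params))
}

# CSV with a leading provenance comment line (read back with comment.char = "#")
write_csv_prov <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double",
                     eol = "\r\n")
  invisible(path)
}

log_info <- function(...) message("[gepnetcea] ", sprintf(...))

#' Base-case report
#'
#' Runs both strategies at the configured parameters, writes per-strategy
#' cohort traces (\code{trace_SSA.csv}, \code{trace_DELAY.csv}), a results
#' table (\code{base_case.csv}: cost, incremental cost, LY, incremental LY,
#' QALY, incremental QALY, ICER, NET-death percentages) and a JSON
#' serialization of the comparison (\code{cea_result.json}), and logs the
#' effective parameters to stderr.
#'
#' @param config A \code{run_config}.
#' @return The \code{cea_result}, invisibly.
#' @export
cmd_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  log_info("base case: ages %g-%g, discount %g%%, WTP $%g/QALY",
           p$start_age, p$horizon_age, 100 * p$discount_annual, p$wtp)
  log_info("params md5 %s", params_hash(p))
  res <- NULL
  for (lab in strategy_labels()) {
    model <- build_strategy(p, lab, config$lt, combine = config$combine)
    trace <- run_cohort(model)
    write_trace(trace, file.path(config$out_dir,
                                 sprintf("trace_%s.csv", lab)))
  }
  ssa <- run_strategy(p, "SSA", config$lt, combine = config$combine)
  delay <- run_strategy(p, "DELAY", config$lt, combine = config$combine)
  res <- compare_strategies(ssa, delay, wtp = p$wtp)
  write_csv_prov(cea_table(res), file.path(config$out_dir, "base_case.csv"),
                 config)
  write_cea_json(res, file.path(config$out_dir, "cea_result.json"))
  if (res$undefined) {
    log_info("strategies indistinguishable in QALYs; ICER undefined")
  } else {
    log_info("ICER $%.0f/QALY (%s)", res$icer,
             if (isTRUE(res$cost_effective_at_wtp)) "cost-effective"
             else "not cost-effective")
  }
  invisible(res)
}

#' Tornado report
#'
#' Writes \code{tornado.csv}: one row per sensitivity parameter with its low
#' and high input, the ICER at each, and the bar width, sorted widest first.
#'
#' @param config A \code{run_config}.
#' @return The \code{tornado} data frame, invisibly.
#' @export
cmd_tornado <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tor <- one_way_dsa(config$params, config$lt, combine = config$combine)
  write_csv_prov(as.data.frame(tor), file.path(config$out_dir, "tornado.csv"),
                 config)
  log_info("tornado: widest bar %s (ICER %.0f-%.0f)", tor$parameter[1L],
           min(tor$icer_low[1L], tor$icer_high[1L]),
           max(tor$icer_low[1L], tor$icer_high[1L]))
  invisible(tor)
}

#' Threshold-price report
#'
#' Solves for the SSA monthly cost meeting the WTP threshold and writes
#' \code{threshold.csv}.
#'
#' @param config A \code{run_config}.
#' @param target Parameter to solve for (default \code{"cost_ssa_month"}).
#' @return The threshold price, invisibly.
#' @export
cmd_threshold <- function(config, target = "cost_ssa_month") {
  stopifnot(inherits(config, "run_config"))
  thr <- threshold_price(config$params, config$lt, wtp = config$params$wtp,
                         target = target, combine = config$combine)
  write_csv_prov(data.frame(target = target, wtp = config$params$wtp,
                            threshold = thr),
                 file.path(config$out_dir, "threshold.csv"), config)
  log_info("threshold %s = $%.2f at WTP $%g/QALY", target, thr,
           config$params$wtp)
  invisible(thr)
}

#' PSA report
#'
#' Runs the probabilistic sensitivity analysis at the configured seed and
#' iteration count and writes \code{psa.csv} (iteration, incremental cost,
#' incremental QALYs) and \code{ceac.csv} (WTP grid, probability SSA is
#' cost-effective).
#'
#' @param config A \code{run_config}.
#' @return The \code{psa_result}, invisibly.
#' @export
cmd_psa <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_info("PSA: %d iterations, seed %d", config$n_psa_iterations, config$seed)
  psa <- run_psa(config$params, config$lt,
                 n_iterations = config$n_psa_iterations, seed = config$seed,
                 combine = config$combine)
  write_csv_prov(as.data.frame(psa), file.path(config$out_dir, "psa.csv"),
                 config)
  cv <- ceac(psa, config$wtp_grid)
  write_csv_prov(cv, file.path(config$out_dir, "ceac.csv"), config)
  log_info("P(cost-effective at WTP $%g) = %.4f", config$params$wtp,
           psa_ce_fraction(psa, config$params$wtp))
  invisible(psa)
}
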