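#' Configuration for the end-to-end analysis pipeline
#'
#' Exactly one of `input` (a records CSV path) or `scenario` (a
#' [simulation_scenario()], or the string `"replica"` for the packaged
#' study replica) must be supplied.
#'
#' @param input Path to a records CSV, or `NULL`.
#' @param scenario A scenario object, `"replica"`, or `NULL`.
#' @param p0,p1,alpha,beta Design parameters (see [cusum_params()]).
#' @param midazolam_threshold,fentanyl_threshold Dose cutpoints (mg, µg).
#' @param unit Analysis unit: `"node"` or `"case"`.
#' @param method Regression method: `"wald_ml"` or `"firth"`.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed (used when generating from a scenario).
#' @param charts Export PNG charts? Default `FALSE`.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL,
                            p0 = 0.1, p1 = 0.2, alpha = 0.1, beta = 0.1,
                            midazolam_threshold = 10,
                            fentanyl_threshold = 300,
                            unit = c("node", "case"),
                            method = c("wald_ml", "firth"),
                            out_dir = "cusumlc-report", seed = 1L,
                            charts = FALSE) {
  if (is.null(input) == is.null(scenario))
    stop("exactly one of 'input' and 'scenario' must be set", call. = FALSE)
  if (!is.null(scenario) && is.character(scenario)) {
    if (!identical(scenario, "replica"))
      stop("unknown scenario reference: ", scenario, call. = FALSE)
  } else if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "simulation_scenario"))
  }
  structure(list(
    input = input, scenario = scenario,
    params = cusum_params(p0, p1, alpha, beta),
    midazolam_threshold = as.numeric(midazolam_threshold),
    fentanyl_threshold = as.numeric(fentanyl_threshold),
    unit = match.arg(unit), method = match.arg(method),
    out_dir = out_dir, seed = as.integer(seed), charts = isTRUE(charts)
  ), class = "pipeline_config")
}

scenario_to_list <- function(sc) {
  list(
    operators = lapply(sc$operators, function(op)
      list(id = op$id, n_cases = op$n_cases,
           phases = list(n_attempts = op$phases$n_attempts,
                         p_fail = op$phases$p_fail))),
    covariates = sc$covariates,
    nodes_per_case = as.list(sc$nodes_per_case),
    seed = sc$seed
  )
}

list_to_scenario <- function(x) {
  simulation_scenario(
    operators = lapply(x$operators, function(op)
      list(id = op$id, n_cases = op$n_cases,
           phases = data.frame(n_attempts = unlist(op$phases$n_attempts),
                               p_fail = unlist(op$phases$p_fail)))),
    covariates = lapply(x$covariates, function(v) lapply(v, unlist)),
    nodes_per_case = unlist(x$nodes_per_case),
    seed = x$seed
  )
}

config_to_list <- function(config) {
  sc <- config$scenario
  list(
    input = config$input,
    scenario = if (is.character(sc) || is.null(sc)) sc else
      scenario_to_list(sc),
    p0 = config$params$p0, p1 = config$params$p1,
    alpha = config$params$alpha, beta = config$params$beta,
    midazolam_threshold = config$midazolam_threshold,
    fentanyl_threshold = config$fentanyl_threshold,
    unit = config$unit, method = config$method,
    seed = config$seed, charts = config$charts
  )
}

#' Read a pipeline configuration from JSON
#'
#' Reads the `effective_config.json` written by [run_pipeline()] (or any file
#' in the same layout); re-running with it reproduces the bundle.
#'
#' @param path Path to the JSON config.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  scen <- x$scenario
  if (!is.null(scen) && !is.character(scen))
    scen <- list_to_scenario(scen)
  if (is.character(scen)) scen <- scen[[1]]
  pipeline_config(
    input = if (is.null(x$input)) NULL else x$input[[1]],
    scenario = scen,
    p0 = x$p0[[1]], p1 = x$p1[[1]], alpha = x$alpha[[1]], beta = x$beta[[1]],
    midazolam_threshold = x$midazolam_threshold[[1]],
    fentanyl_threshold = x$fentanyl_threshold[[1]],
    unit = x$unit[[1]], method = x$method[[1]],
    out_dir = if (is.null(x$out_dir)) "cusumlc-report" else x$out_dir[[1]],
    seed = x$seed[[1]], charts = x$charts[[1]]
  )
}

#' Run the full monitoring and environment-analysis pipeline
#'
#' Reads (or generates) the sampling-attempt records, derives the CUSUM
#' constants, builds per-operator and pooled institutional charts, classifies
#' proficiency states, segments the pooled chart into chronological intervals,
#' fits the learning-environment regression contrasting the worsening interval
#' against the others, and writes a report bundle:
#' `constants.json`, `trajectory_<operator>.csv` (one per operator) and
#' `trajectory_pooled.csv`, `segments.csv`, `intervals.csv`,
#' `regression.csv` + `regression.json`, `effective_config.json`,
#' `run_log.json`, and (optionally) one PNG chart per trajectory. Re-running
#' with an identical config and input reproduces the bundle bit-identically
#' except for the timestamp in the run log (the output directory is not part
#' of the effective config, so bundles written to different directories also
#' compare identical).
#'
#' If the segmentation yields no worsening interval the regression outcome is
#' degenerate; the error is recorded in `regression.json` and the run log, and
#' the remaining artifacts are still produced.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with the in-memory objects (`records`,
#'   `constants`, `charts`, `intervals`, `fit`) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  log <- list(seed = config$seed)

  if (!is.null(config$input)) {
    records <- read_records(config$input)
    log$input <- config$input
  } else {
    scen <- config$scenario
    if (is.character(scen)) scen <- replica_scenario(seed = config$seed)
    records <- generate_cohort(scen, seed = config$seed)
    log$scenario_operators <- length(scen$operators)
  }
  pooled <- pool_institutional(records)
  log$n_records <- nrow(pooled)
  log$n_cases <- length(unique(pooled$case_id))
  log$n_operators <- length(unique(pooled$operator_id))

  constants <- cusum_constants(config$params)
  jsonlite::write_json(unclass(constants)[c("P", "Q", "s",
                                            "failure_increment", "a", "b",
                                            "H0", "H1")],
                       path("constants.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, path("constants.json"))

  ops <- unique(pooled$operator_id)
  charts <- list()
  seg_rows <- list()
  for (id in c(as.character(ops), ".pooled")) {
    sub <- if (id == ".pooled") pooled else
      pooled[pooled$operator_id == id, , drop = FALSE]
    nm <- if (id == ".pooled") "pooled" else id
    ch <- cusum_chart(sub$outcome, constants, id = nm)
    charts[[nm]] <- ch
    tr <- as.data.frame(ch)
    f <- path(sprintf("trajectory_%s.csv", nm))
    utils::write.csv(tr, f, row.names = FALSE)
    files <- c(files, f)
    seg <- ch$segments
    if (nrow(seg)) seg$chart <- nm
    seg_rows[[nm]] <- seg
    if (config$charts) {
      pf <- path(sprintf("chart_%s.png", nm))
      grDevices::png(pf, width = 900, height = 500)
      plot(ch)
      grDevices::dev.off()
      files <- c(files, pf)
    }
  }
  segments_all <- do.call(rbind, seg_rows)
  utils::write.csv(segments_all, path("segments.csv"), row.names = FALSE)
  files <- c(files, path("segments.csv"))

  intervals <- segment_intervals(charts$pooled$segments, pooled$case_index)
  utils::write.csv(intervals, path("intervals.csv"), row.names = FALSE)
  files <- c(files, path("intervals.csv"))
  log$n_intervals <- nrow(intervals)
  log$interval_labels <- intervals$label

  frame <- build_analysis_frame(pooled, intervals,
                                midazolam_threshold = config$midazolam_threshold,
                                fentanyl_threshold = config$fentanyl_threshold,
                                unit = config$unit)
  log$n_analysis_rows <- nrow(frame)
  log$n_dropped_missing <- attr(frame, "n_dropped")

  fit <- tryCatch(fit_environment(frame, method = config$method),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    log$regression_error <- conditionMessage(fit)
    jsonlite::write_json(list(error = conditionMessage(fit)),
                         path("regression.json"), auto_unbox = TRUE)
    utils::write.csv(data.frame(error = conditionMessage(fit)),
                     path("regression.csv"), row.names = FALSE)
    fit <- NULL
  } else {
    res <- fit$table
    res$method <- fit$method
    res$n_rows <- fit$n_rows
    utils::write.csv(res, path("regression.csv"), row.names = FALSE)
    jsonlite::write_json(list(method = fit$method, response = fit$response,
                              n_rows = fit$n_rows,
                              n_dropped = fit$n_dropped,
                              caveat = paste("within-case clustering of",
                                             "sampled nodes is not adjusted for"),
                              terms = res),
                         path("regression.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  files <- c(files, path("regression.csv"), path("regression.json"))

  jsonlite::write_json(config_to_list(config), path("effective_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, path("effective_config.json"))
  log$config_md5 <- unname(tools::md5sum(path("effective_config.json")))
  log$timestamp <- format(t0, "%Y-%m-%dT%H:%M:%S%z")
  log$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(log, path("run_log.json"), auto_unbox = TRUE)
  files <- c(files, path("run_log.json"))

  invisible(list(records = pooled, constants = constants, charts = charts,
                 intervals = intervals, fit = fit, files = files,
                 log = log))
}
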