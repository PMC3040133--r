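#' Assemble a Table-style fit report
#'
#' One row per model: raw and normalized fit error, raw and normalized
#' leave-one-out prediction error, and the fitted parameters, rounded to 3
#' significant figures for reporting.
#'
#' @param fits named list of [fit_model()] results (after
#'   [compare_models()]).
#' @param loos optional named list of [loo_prediction_error()] results
#'   (after [normalize_pe()]), matching `fits` by model.
#' @return A data frame with columns `model`, `fit_err`, `norm_fit_err`,
#'   `pred_err`, `norm_pred_err`, `parameters` (a single formatted string).
#' @export
fit_report <- function(fits, loos = NULL) {
  rows <- lapply(fits, function(f) {
    loo <- if (!is.null(loos)) loos[[f$model]] else NULL
    nm <- param_names(f$model)
    data.frame(model = f$model,
               fit_err = signif(f$raw_error, 3),
               norm_fit_err = signif(f$normalized_error, 3),
               pred_err = if (is.null(loo)) NA_real_ else signif(loo$prediction_error, 3),
               norm_pred_err = if (is.null(loo)) NA_real_ else signif(loo$normalized_pe, 3),
               parameters = paste(sprintf("%s=%.3g", nm, unlist(f$params[nm])),
                                  collapse = ", "))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Validate a pipeline configuration list against the known schema.
check_config <- function(config) {
  known <- c("command", "dataset", "generate", "model", "models", "params",
             "shared", "fit", "simulate", "seed", "output")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  cmd <- config$command
  if (is.null(cmd) || !cmd %in% c("generate", "fit", "crossval", "simulate", "report"))
    stop("config 'command' must be one of: generate, fit, crossval, simulate, report")
  config
}

config_shared <- function(config) {
  do.call(shared_rates, as.list(config$shared %||% list()))
}

config_options <- function(config, seed) {
  opts <- as.list(config$fit %||% list())
  opts$seed <- seed
  do.call(fit_options, opts)
}

config_dataset <- function(config, shared, seed) {
  if (!is.null(config$dataset)) {
    read_dataset(config$dataset$path,
                 level = config$dataset$level %||% "mRNA")
  } else if (!is.null(config$generate)) {
    g <- config$generate
    generate_dataset(g$model, as.list(g$params), shared,
                     doses = g$doses %||% paper_dose_grid(),
                     noise = noise_model(g$cv %||% 0.1,
                                         g$n_replicates %||% 3L),
                     seed = g$seed %||% seed,
                     level = g$level %||% "mRNA")
  } else stop("config needs either a 'dataset' or a 'generate' block")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured analysis pipeline
#'
#' Executes one of five commands described by a configuration list or YAML
#' file:
#' \describe{
#'   \item{generate}{write a synthetic dose-response dataset (and its
#'     replicate-level draws) to CSV.}
#'   \item{fit}{fit the requested models, normalize errors, write the fit
#'     report CSV.}
#'   \item{crossval}{fit plus leave-one-out prediction error per model,
#'     normalized; report CSV includes the PE columns.}
#'   \item{simulate}{integrate a time course at one dose and write it as
#'     CSV.}
#'   \item{report}{alias for crossval (the full comparison table).}
#' }
#' A plain-text log (seed, options, stages) is written next to the outputs.
#'
#' @param config configuration list, or path to a YAML file.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the computed objects and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- check_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  shared <- config_shared(config)
  logfile <- file.path(out_dir, "pipeline.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logfile,
                               append = TRUE)
  cat(sprintf("# rnaikin pipeline: command=%s seed=%d\n", config$command, seed),
      file = logfile)
  paths <- character(0)
  result <- list()

  if (config$command == "generate") {
    ds <- config_dataset(config, shared, seed)
    p <- file.path(out_dir, config$output %||% "dataset.csv")
    write_dataset(ds, p)
    rp <- sub("\\.csv$", "_replicates.csv", p)
    if (!is.null(attr(ds, "replicates"))) write_replicates(ds, rp)
    logline("wrote %s (%d doses)", p, nrow(ds))
    paths <- c(paths, p)
    result$dataset <- ds
  } else if (config$command == "simulate") {
    s <- config$simulate %||% stop("simulate command needs a 'simulate' block")
    tr <- simulate_timecourse(s$model, as.list(s$params), shared,
                              xs = s$xs,
                              t_grid = seq(0, s$t_max %||% 2880,
                                           by = s$t_step %||% 60))
    p <- file.path(out_dir, config$output %||% "trajectory.csv")
    write_trajectory(tr, p)
    logline("wrote %s (%d time points, xs=%g)", p, nrow(tr), s$xs)
    paths <- c(paths, p)
    result$trajectory <- tr
  } else {  # fit / crossval / report
    ds <- config_dataset(config, shared, seed)
    models <- config$models %||% MODEL_IDS
    options <- config_options(config, seed)
    logline("dataset: %d doses, level %s", nrow(ds), attr(ds, "level"))
    logline("fit options: restarts=%d seed=%d constrain_h_ge_1=%s",
            options$restarts, options$seed, options$constrain_h_ge_1)
    fits <- fit_all_models(ds, shared, options, models = models)
    loos <- NULL
    if (config$command %in% c("crossval", "report")) {
      loos <- lapply(models, loo_prediction_error, dataset = ds,
                     shared = shared, options = options)
      loos <- normalize_pe(loos)
    }
    report <- fit_report(fits, loos)
    p <- file.path(out_dir, config$output %||% "fit_report.csv")
    utils::write.csv(report, p, row.names = FALSE)
    logline("wrote %s", p)
    paths <- c(paths, p)
    result$fits <- fits
    result$loos <- loos
    result$report <- report
  }
  result$paths <- paths
  invisible(result)
}
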