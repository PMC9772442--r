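#' Pipeline run configuration
#'
#' Orchestration settings shared by the `run_*` commands and the `venpk`
#' command-line front-end (installed under `inst/cli/`).  Any field can be
#' supplied through a YAML config file; command arguments override file
#' values.
#'
#' @param out_dir output directory (created if missing).
#' @param dataset path of the dataset CSV to read or write.
#' @param seed master seed.
#' @param ka absorption rate constant used (and fixed) in estimation.
#' @param ka_multipliers sensitivity multipliers for [run_fit()]'s ka
#'   sensitivity analysis.
#' @param ka_sensitivity logical: run the ka sensitivity fits.
#' @param npde_k NPDE replicate count (floor 100).
#' @param fast logical: screening tolerances for covariate search.
#' @param generator a [generator_config()] (for [run_simulate()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = "venpk-out",
                       dataset = file.path(out_dir, "dataset.csv"),
                       seed = 978202,
                       ka = 0.63,
                       ka_multipliers = c(0.5, 2),
                       ka_sensitivity = FALSE,
                       npde_k = 1000,
                       fast = TRUE,
                       generator = NULL) {
  if (any(ka_multipliers <= 0)) stop("ka multipliers must be positive",
                                     call. = FALSE)
  if (npde_k < 100) npde_k <- 100
  if (is.null(generator)) generator <- generator_config(seed = seed)
  structure(list(out_dir = out_dir, dataset = dataset, seed = seed,
                 ka = ka, ka_multipliers = ka_multipliers,
                 ka_sensitivity = ka_sensitivity, npde_k = npde_k,
                 fast = fast, generator = generator),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the yaml package", call. = FALSE)
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  y$generator <- NULL
  cfg <- do.call(run_config, y)
  if (!is.null(gen_args))
    cfg$generator <- do.call(generator_config,
                             c(gen_args, list(seed = cfg$seed)))
  cfg
}

.log_line <- function(config, stage, msg) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile()
  saveRDS(config[setdiff(names(config), "generator")], tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  line <- sprintf("[%s] stage=%s seed=%d config=%s venpk=%s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  config$seed, substr(hash, 1, 8),
                  as.character(utils::packageVersion("venpk")), msg)
  message(line)
  cat(line, "\n", file = file.path(config$out_dir, "venpk.log"),
      append = TRUE)
}

#' Simulate the combined synthetic dataset to disk
#'
#' @param config a [run_config()].
#' @return Invisibly, paths of the dataset CSV and truth JSON.
#' @export
run_simulate <- function(config = run_config()) {
  dir.create(dirname(config$dataset), recursive = TRUE, showWarnings = FALSE)
  .log_line(config, "simulate", paste("writing", config$dataset))
  sim <- generate_combined(config$generator, seed = config$seed)
  write_pk_dataset(sim$dataset, config$dataset)
  truth_path <- file.path(config$out_dir, "truth.json")
  write_truth(sim$truth, truth_path)
  invisible(c(dataset = config$dataset, truth = truth_path))
}

#' Fit the base (or final) model to a dataset on disk
#'
#' Fits by FOCEI with ka fixed at `config$ka`; with
#' `config$ka_sensitivity = TRUE` also refits with ka scaled by each of
#' `config$ka_multipliers` and reports relative parameter deltas.
#'
#' @param config a [run_config()].
#' @param model a [model_spec()]; defaults to the covariate-free base model.
#' @return The [focei_fit()] (with `ka_sensitivity` attribute when
#'   requested), invisibly; reports are written to `out_dir`.
#' @export
run_fit <- function(config = run_config(), model = NULL) {
  ds <- read_pk_dataset(config$dataset, config$generator$limits)
  if (is.null(model)) {
    p <- default_structural_params()
    p$ka <- config$ka
    model <- model_spec(params = do.call(structural_params,
                                         p[.param_names]))
  }
  .log_line(config, "fit", paste("dataset", config$dataset))
  ctrl <- focei_control(fast = config$fast)
  fit <- focei_fit(ds, model, control = ctrl)
  if (fit$convergence != 0)
    warning("fit did not converge: ", fit$message, call. = FALSE)
  write_fit_report(fit, file.path(config$out_dir, "fit"))
  if (config$ka_sensitivity) {
    base_est <- .natural_estimates(fit)
    sens <- list()
    for (mult in config$ka_multipliers) {
      m2 <- model
      m2$params$ka <- config$ka * mult
      f2 <- focei_fit(ds, m2, control = ctrl, start = fit)
      sens[[as.character(mult)]] <-
        (.natural_estimates(f2) - base_est) / base_est
    }
    attr(fit, "ka_sensitivity") <- sens
    jsonlite::write_json(sens, file.path(config$out_dir,
                                         "ka_sensitivity.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  .log_line(config, "fit", sprintf("OFV %.3f convergence %d", fit$ofv,
                                   fit$convergence))
  invisible(fit)
}

#' Run the stepwise covariate search on a dataset on disk
#'
#' @param config a [run_config()].
#' @param candidates candidate grid; defaults to
#'   [default_candidate_grid()].
#' @return The `scm_result`, invisibly; the trace is written to `out_dir`.
#' @export
run_scm <- function(config = run_config(), candidates = NULL) {
  ds <- read_pk_dataset(config$dataset, config$generator$limits)
  p <- default_structural_params()
  p$ka <- config$ka
  base <- model_spec(params = do.call(structural_params, p[.param_names]))
  if (is.null(candidates)) candidates <- default_candidate_grid(ds)
  .log_line(config, "scm", sprintf("%d candidates", length(candidates)))
  res <- stepwise_search(ds, base, candidates,
                         control = focei_control(fast = config$fast))
  write_scm_trace(res$trace, file.path(config$out_dir, "scm_trace"))
  write_fit_report(res$fit, file.path(config$out_dir, "final_model"))
  .log_line(config, "scm", paste("retained:",
                                 paste(res$selected, collapse = ", ")))
  invisible(res)
}

#' Run model diagnostics on a dataset on disk
#'
#' @param config a [run_config()].
#' @param fit a [focei_fit()]; refitted from the dataset if missing.
#' @param model model for the (re)fit when `fit` is missing.
#' @return List with `gof` and `npde`, invisibly; panels written to
#'   `out_dir/diagnostics`.
#' @export
run_diagnose <- function(config = run_config(), fit = NULL, model = NULL) {
  ds <- read_pk_dataset(config$dataset, config$generator$limits)
  if (is.null(fit)) fit <- run_fit(config, model)
  .log_line(config, "diagnose", sprintf("K = %d", config$npde_k))
  gof <- gof_table(ds, fit)
  nr <- npde(ds, fit, K = config$npde_k, seed = config$seed)
  diagnostic_export(gof, nr, file.path(config$out_dir, "diagnostics"))
  .log_line(config, "diagnose",
            sprintf("npde mean %.3f var %.3f", nr$mean, nr$variance))
  invisible(list(gof = gof, npde = nr))
}
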