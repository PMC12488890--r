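#' Experiment configuration
#'
#' A declarative description of a full run: how to obtain the cohort (a
#' generator preset or CSV paths), the task, the backend, and the evaluation
#' controls. One global seed derives every stage seed deterministically.
#' Round-trips through YAML for the command-line interface.
#'
#' @param cohort Either a [cohort_config()] (simulate) or a list
#'   `list(observations = path, statics = path)` (ingest CSVs).
#' @param task A [task_config()].
#' @param backend_spec List: `name` (`"echo"`, `"tinylm"`) plus constructor
#'   arguments.
#' @param k Sampled trajectories per forecast.
#' @param trend_window Trend lookback window (task time units).
#' @param fractions,strata Splitting controls.
#' @param registry Optional [variable_registry()] (enables reference-range
#'   metrics).
#' @param seed Global seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, task, backend_spec = list(name = "echo"),
                              k = 30L, trend_window = 3L,
                              fractions = c(train = 0.8, validation = 0.1,
                                            test = 0.1),
                              strata = NULL, registry = NULL, seed = 1L) {
  stopifnot(inherits(task, "task_config"))
  structure(list(cohort = cohort, task = task, backend_spec = backend_spec,
                 k = as.integer(k), trend_window = as.integer(trend_window),
                 fractions = fractions, strata = strata, registry = registry,
                 seed = seed),
            class = "experiment_config")
}

make_backend <- function(spec) {
  args <- spec[setdiff(names(spec), "name")]
  switch(spec$name,
         echo = do.call(backend_echo, args),
         tinylm = do.call(backend_tinylm, args),
         stop("unknown backend: ", spec$name))
}

#' Run a full forecasting experiment
#'
#' Executes the pipeline end to end -- simulate/ingest, bin, filter, split,
#' landmark, encode, fine-tune, sample, aggregate, evaluate -- and, when an
#' output directory is given, writes every artifact (split manifest, outlier
#' bounds, forecasts, metric reports for the backend and the two reference
#' forecasters, a structured JSONL log, and a manifest with file hashes).
#' Byte-reproducible from config + seed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional artifact directory (created).
#' @param seed Overrides the config seed.
#' @return List with the fitted `model`, `forecasts`, and `reports` (named:
#'   `backend`, `copy_forward`, `linear`), plus `paths` when writing.
#' @export
run_experiment <- function(config, out_dir = NULL, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- seed %||% config$seed
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }

  if (inherits(config$cohort, "cohort_config")) {
    sim <- simulate_cohort(config$cohort, seed = derive_seed(seed, "cohort"))
    raw <- sim$cohort
    note("simulate", n_patients = config$cohort$n_patients,
         n_observations = nrow(raw$observations))
  } else {
    raw <- read_cohort(config$cohort$observations, config$cohort$statics)
    note("ingest", n_observations = nrow(raw$observations))
  }

  model <- twin_forecaster(raw, config$task,
                           registry = config$registry %||% NULL,
                           backend = make_backend(config$backend_spec),
                           fractions = config$fractions,
                           strata = config$strata,
                           k = config$k, seed = seed)
  note("fit", backend = config$backend_spec$name,
       n_train = length(model$examples$train),
       n_test = length(model$examples$test))

  test_ex <- model$examples$test
  forecasts <- predict(model, newdata = test_ex, k = config$k,
                       seed = derive_seed(seed, "predict"))
  ens <- attr(forecasts, "ensembles")
  n_failed <- sum(vapply(ens, function(e) {
    sum(vapply(e$decoded, `[[`, character(1L), "status") == "failed")
  }, integer(1L)))
  note("sample", k = config$k, n_examples = length(test_ex),
       n_failed_parses = n_failed)

  cf <- lapply(test_ex, copy_forward_forecast, train_stats = model$train_stats)
  lin <- linear_reference_forecast(model$examples$train, test_ex,
                                   train_stats = model$train_stats)
  cfg <- metric_config(sigma = model$train_stats$sigma,
                       registry = model$registry,
                       trend_window = config$trend_window)
  reports <- list(backend = evaluate_forecasts(forecasts, test_ex, cfg),
                  copy_forward = evaluate_forecasts(cf, test_ex, cfg),
                  linear = evaluate_forecasts(lin, test_ex, cfg))
  note("evaluate",
       backend_scaled_mae = mean(reports$backend$errors$scaled_MAE),
       copy_forward_scaled_mae = mean(reports$copy_forward$errors$scaled_MAE))

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    jsonlite::write_json(model$splits, p("splits.json"), auto_unbox = FALSE)
    if (!is.null(model$bounds)) {
      jsonlite::write_json(model$bounds, p("outlier_bounds.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
    }
    fc_records <- lapply(seq_along(test_ex), function(i) {
      list(patient_id = test_ex[[i]]$patient_id, t0 = test_ex[[i]]$t0,
           forecast = lapply(forecasts[[i]], as.list))
    })
    write_jsonl(fc_records, p("forecasts.jsonl"))
    for (nm in names(reports)) {
      write_metric_report(reports[[nm]], p(paste0("metrics_", nm, ".json")))
    }
    write_jsonl(log, p("log.jsonl"))
    files <- setdiff(list.files(out_dir), "manifest.json")
    manifest <- list(seed = seed,
                     files = lapply(files, function(f) {
                       list(file = f,
                            md5 = unname(tools::md5sum(file.path(out_dir, f))))
                     }))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    paths <- p(c("splits.json", "forecasts.jsonl", "manifest.json"))
  }

  list(model = model, forecasts = forecasts, reports = reports,
       log = log, paths = paths)
}

#' Robustness ablation over misspellings or masking
#'
#' Repeats the evaluation of a fitted forecaster on a seeded subsample of
#' test patient samples while perturbing the model input along one axis:
#' injected misspellings (`n` edit operations on the prompt text) or
#' additional masking of history observations (probability per observation,
#' on top of the data's own missingness). The perturbation touches only the
#' model input -- truth and evaluation constants are untouched -- and grid
#' value 0 reproduces the unperturbed report exactly.
#'
#' @param model A fitted `twin_forecaster`.
#' @param axis `"misspellings"` or `"masking"`.
#' @param grid Numeric grid: operation counts, or masking fractions.
#' @param n_samples Test patient samples per grid point (study protocol:
#'   200).
#' @param k Trajectories per forecast.
#' @param trend_window Trend lookback window.
#' @param seed Seed (subsampling, perturbation, and sampling).
#' @return List: `reports` (one `metric_report` per grid value, named),
#'   `summary` (data.frame of grid value and mean scaled MAE).
#' @export
run_ablation <- function(model, axis = c("misspellings", "masking"),
                         grid, n_samples = 200L, k = model$k,
                         trend_window = 3L, seed = 1L) {
  axis <- match.arg(axis)
  if (length(grid) == 0L) stop("ablation grid is empty")
  test_ex <- model$examples$test
  if (length(test_ex) > n_samples) {
    idx <- with_seed(derive_seed(seed, "subsample"),
                     sample(seq_along(test_ex), n_samples))
    test_ex <- test_ex[sort(idx)]
  }
  cfg <- metric_config(sigma = model$train_stats$sigma,
                       registry = model$registry,
                       trend_window = trend_window)
  reports <- list()
  for (g in grid) {
    forecasts <- vector("list", length(test_ex))
    for (i in seq_along(test_ex)) {
      ex <- test_ex[[i]]
      if (axis == "masking" && g > 0) {
        ex <- mask_observations(ex, g,
                                seed = derive_seed(seed, paste0("mask", g, "_", i)))
      }
      enc <- encode_example(ex, model$template, observed_only = FALSE)
      if (axis == "misspellings" && g > 0) {
        enc$input <- inject_misspellings(
          enc$input, g, seed = derive_seed(seed, paste0("spell", g, "_", i)))
      }
      ensemble <- sample_trajectories(model$backend, enc, k = k,
                                      seed = derive_seed(seed, paste0("sample", i)))
      fallback <- copy_forward_forecast(test_ex[[i]], model$train_stats)
      forecasts[[i]] <- aggregate_mean(ensemble, fallback = fallback)
    }
    reports[[as.character(g)]] <- evaluate_forecasts(forecasts, test_ex, cfg)
  }
  summary <- data.frame(
    grid = grid,
    mean_scaled_mae = vapply(reports, function(r) {
      mean(r$errors$scaled_MAE, na.rm = TRUE)
    }, numeric(1L)))
  list(axis = axis, reports = reports, summary = summary)
}

#' Read / write experiment configs as YAML
#'
#' @param path YAML file.
#' @return `read_experiment_config` returns an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort$preset)) {
    switch(y$cohort$preset,
           learnable = do.call(learnable_cohort_config,
                               y$cohort[setdiff(names(y$cohort), "preset")]),
           default = do.call(cohort_config,
                             y$cohort[setdiff(names(y$cohort), "preset")]),
           stop("unknown cohort preset: ", y$cohort$preset))
  } else if (!is.null(y$cohort$observations)) {
    y$cohort
  } else {
    do.call(cohort_config, y$cohort)
  }
  task <- do.call(task_config, y$task)
  registry <- if (!is.null(y$registry) && y$registry == "nsclc") {
    nsclc_registry()
  }
  experiment_config(cohort = cohort, task = task,
                    backend_spec = y$backend %||% list(name = "echo"),
                    k = y$k %||% 30L,
                    registry = registry,
                    trend_window = y$trend_window %||% 3L,
                    fractions = if (!is.null(y$fractions)) unlist(y$fractions)
                                else c(train = 0.8, validation = 0.1, test = 0.1),
                    strata = y$strata,
                    seed = y$seed %||% 1L)
}
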