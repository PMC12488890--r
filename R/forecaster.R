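#' Fit a digital-twin trajectory forecaster
#'
#' The package's central fitting function. Starting from a raw long-format
#' cohort it runs the deterministic preparation pipeline -- temporal binning
#' by last observed value, patient-level train/validation/test splitting,
#' two-step outlier filtering with training-split statistics, quantization of
#' target values to the reporting precision (making the text channel
#' lossless), landmark example construction -- then serializes the training
#' examples to input/target text pairs and fine-tunes the chosen generative
#' backend on them with an output-masked loss.
#'
#' @param cohort A raw [cohort()] (or an already binned one).
#' @param task A [task_config()].
#' @param registry Optional [variable_registry()] (enables reference-range
#'   evaluation and zero-shot prompts).
#' @param backend A backend, e.g. [backend_echo()] or [backend_tinylm()].
#' @param template A [prompt_template()].
#' @param fractions Split fractions (named, summing to 1; must contain
#'   `train` and `test`).
#' @param strata Optional static attributes for stratified splitting.
#' @param outlier_filter Apply the two-step outlier procedure.
#' @param k Default number of sampled trajectories per forecast.
#' @param seed Global seed; all stage seeds derive from it.
#' @return An object of class `twin_forecaster`.
#' @export
twin_forecaster <- function(cohort, task, registry = NULL,
                            backend = backend_echo(),
                            template = prompt_template(),
                            fractions = c(train = 0.8, validation = 0.1,
                                          test = 0.1),
                            strata = NULL, outlier_filter = TRUE,
                            k = 30L, seed = 1L) {
  stopifnot(inherits(cohort, "twin_cohort"), inherits(task, "task_config"))
  binned <- bin_last_observed(cohort, task$bin_width)
  splits <- split_patients(binned, fractions, strata = strata,
                           seed = derive_seed(seed, "split"))

  bounds <- NULL
  if (outlier_filter) {
    filt <- filter_outliers(binned, task$targets, train_ids = splits$train)
    binned <- filt$cohort
    bounds <- filt$bounds
  }
  binned <- quantize_cohort(binned, task$targets, template$precision)

  examples <- lapply(splits, function(ids) {
    make_examples(cohort_subset(binned, ids), task)
  })

  # sigma: training-split sd of target values after outlier filtering;
  # median: copy-forward fallback, at reporting precision
  train_obs <- binned$observations[
    binned$observations$patient_id %in% splits$train, , drop = FALSE]
  tnum <- suppressWarnings(as.numeric(train_obs$value))
  sigma <- vapply(task$targets, function(v) {
    stats::sd(tnum[train_obs$variable == v & !is.na(tnum)])
  }, numeric(1L))
  # median fallback pooled over the training examples' observed future
  # values: the same multiset the backend sees in the target texts, so the
  # echo baseline and the native copy-forward agree bit for bit
  truth_pool <- list()
  for (ex in examples$train) {
    for (v in names(ex$truth)) {
      truth_pool[[v]] <- c(truth_pool[[v]], unname(ex$truth[[v]]))
    }
  }
  medians <- vapply(task$targets, function(v) {
    if (is.null(truth_pool[[v]])) return(NA_real_)
    round_half_up(stats::median(truth_pool[[v]]), template$precision)
  }, numeric(1L))
  train_stats <- list(sigma = sigma, median = medians,
                      n_examples = length(examples$train))

  pairs <- lapply(examples$train, encode_example, template = template,
                  observed_only = TRUE)
  if (length(pairs) == 0L) stop("no training examples after preparation")
  backend <- fine_tune(backend, pairs, seed = derive_seed(seed, "finetune"))

  structure(list(backend = backend, template = template, task = task,
                 registry = registry, splits = splits, bounds = bounds,
                 examples = examples, train_stats = train_stats,
                 cohort = binned, k = as.integer(k), seed = seed,
                 call = match.call()),
            class = "twin_forecaster")
}

#' @export
print.twin_forecaster <- function(x, ...) {
  cat("Digital-twin trajectory forecaster\n")
  cat("  backend:   ", class(x$backend)[1L], "\n")
  cat("  targets:   ", paste(x$task$targets, collapse = ", "), "\n")
  cat(sprintf("  horizons:   %d %s steps\n", length(x$task$horizons),
              x$task$unit_label))
  cat(sprintf("  examples:   train %d / validation %d / test %d\n",
              length(x$examples$train),
              length(x$examples$validation %||% list()),
              length(x$examples$test %||% list())))
  invisible(x)
}

#' @export
summary.twin_forecaster <- function(object, ...) {
  print(object)
  cat("\nTraining-split scaling sigma:\n")
  print(round(object$train_stats$sigma, 4))
  if (!is.null(object$backend$loss_curve)) {
    cat("\nFine-tuning loss (per masked token, by epoch):\n")
    print(round(object$backend$loss_curve, 4))
  }
  if (!is.null(object$bounds)) {
    cat("\nOutlier bounds (step 2):\n")
    print(object$bounds[, c("variable", "lo2", "hi2", "n_removed_step1",
                            "degenerate")], row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.twin_forecaster <- function(object, ...) {
  list(sigma = object$train_stats$sigma, median = object$train_stats$median)
}

#' Sample trajectory ensembles from a fitted forecaster
#'
#' `simulate` draws `nsim` stochastic trajectories per patient sample through
#' the text channel (encode, generate, decode), returning the raw ensembles
#' with parse accounting -- the generative analogue of simulating from a
#' fitted model.
#'
#' @param object A `twin_forecaster`.
#' @param nsim Trajectories per example.
#' @param seed Seed.
#' @param newdata List of `forecast_example`s (default: the test split).
#' @param ... Unused.
#' @return List of `trajectory_ensemble` objects.
#' @export
simulate.twin_forecaster <- function(object, nsim = object$k, seed = NULL,
                                     newdata = NULL, ...) {
  examples <- newdata %||% object$examples$test
  lapply(seq_along(examples), function(i) {
    enc <- encode_example(examples[[i]], object$template,
                          observed_only = FALSE)
    sample_trajectories(object$backend, enc, k = nsim,
                        seed = if (is.null(seed)) NULL else
                          derive_seed(seed, paste0("sample", i)))
  })
}

#' Forecast trajectories for new patient samples
#'
#' Encodes each example, samples `k` completions from the backend, decodes
#' them, and aggregates per time point: the arithmetic mean of the parsed
#' samples (`type = "mean"`, the study protocol), or the hindsight-optimal
#' single trajectory (`type = "oracle"`, a theoretical lower bound requiring
#' observed truth). All-failed cells fall back to copy-forward (flagged).
#'
#' @param object A `twin_forecaster`.
#' @param newdata List of `forecast_example`s (default: the test split).
#' @param k Sampled trajectories per example.
#' @param type Aggregation: `"mean"` or `"oracle"`.
#' @param seed Seed for sampling.
#' @param ... Unused.
#' @return List of trajectories parallel to `newdata`, with attribute
#'   `"ensembles"` carrying the raw ensembles and, for `"oracle"`,
#'   `"skipped"` counting examples with no fully parsed sample (those fall
#'   back to the mean aggregate).
#' @export
predict.twin_forecaster <- function(object, newdata = NULL, k = object$k,
                                    type = c("mean", "oracle"), seed = NULL,
                                    ...) {
  type <- match.arg(type)
  examples <- newdata %||% object$examples$test
  ensembles <- simulate(object, nsim = k, seed = seed, newdata = examples)
  skipped <- 0L
  out <- vector("list", length(examples))
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    fallback <- copy_forward_forecast(ex, object$train_stats)
    if (type == "mean") {
      out[[i]] <- aggregate_mean(ensembles[[i]], fallback = fallback)
    } else {
      res <- tryCatch(
        oracle_best_trajectory(ensembles[[i]], ex$truth,
                               object$train_stats$sigma),
        error = function(e) NULL)
      if (is.null(res)) {
        skipped <- skipped + 1L
        out[[i]] <- aggregate_mean(ensembles[[i]], fallback = fallback)
      } else {
        out[[i]] <- res$trajectory
      }
    }
  }
  attr(out, "ensembles") <- ensembles
  if (type == "oracle") attr(out, "skipped") <- skipped
  out
}

#' Residuals of a fitted forecaster
#'
#' Truth minus mean-aggregated prediction over the observed future cells of
#' the evaluation examples.
#'
#' @param object A `twin_forecaster`.
#' @param newdata,k,seed As in [predict.twin_forecaster()].
#' @param ... Unused.
#' @return The evaluation panel data.frame with a `residual` column.
#' @export
residuals.twin_forecaster <- function(object, newdata = NULL, k = object$k,
                                      seed = NULL, ...) {
  examples <- newdata %||% object$examples$test
  forecasts <- predict(object, newdata = examples, k = k, seed = seed)
  panel <- forecast_panel(forecasts, examples)
  panel$residual <- panel$truth - panel$pred
  panel
}

#' Evaluate a fitted forecaster with the full metric suite
#'
#' @param object A `twin_forecaster`.
#' @param newdata Examples to score (default: test split).
#' @param forecasts Optional precomputed trajectories (skips sampling).
#' @param k,seed Sampling controls when `forecasts` is absent.
#' @param trend_window Lookback window for trend AUCs, in task time units.
#' @return A `metric_report`.
#' @export
evaluate_model <- function(object, newdata = NULL, forecasts = NULL,
                           k = object$k, seed = NULL, trend_window = 3L) {
  examples <- newdata %||% object$examples$test
  if (is.null(forecasts)) {
    forecasts <- predict(object, newdata = examples, k = k, seed = seed)
  }
  cfg <- metric_config(sigma = object$train_stats$sigma,
                       registry = object$registry,
                       trend_window = trend_window)
  evaluate_forecasts(forecasts, examples, cfg)
}

#' Plot one forecast against history and truth
#'
#' Base-graphics view of a single patient sample: observed history to the
#' left of the landmark, observed future truth, and the model's aggregated
#' forecast.
#'
#' @param x A `twin_forecaster`.
#' @param example A `forecast_example` (default: first test example).
#' @param variable Target to plot (default: first task target present).
#' @param forecast Optional precomputed trajectory for the example.
#' @param k,seed Sampling controls when `forecast` is absent.
#' @param ... Passed to [plot()].
#' @export
plot.twin_forecaster <- function(x, example = NULL, variable = NULL,
                                 forecast = NULL, k = x$k, seed = NULL, ...) {
  example <- example %||% x$examples$test[[1L]]
  variable <- variable %||% intersect(x$task$targets, names(example$truth))[1L]
  if (is.null(forecast)) {
    forecast <- predict(x, newdata = list(example), k = k, seed = seed)[[1L]]
  }
  hist <- example$history
  hnum <- obs_numeric(hist)
  hsel <- hist$variable == variable & !is.na(hnum)
  tv <- example$truth[[variable]]
  pv <- forecast[[variable]]
  xs <- c(hist$time[hsel], as.integer(names(tv)), as.integer(names(pv)))
  ys <- c(hnum[hsel], as.numeric(tv), as.numeric(pv))
  plot(NA, xlim = range(xs), ylim = range(ys, na.rm = TRUE),
       xlab = paste0("time (", example$unit_label, "s from landmark)"),
       ylab = variable,
       main = paste("Patient", example$patient_id), ...)
  graphics::abline(v = 0, lty = 3, col = "grey50")
  graphics::points(hist$time[hsel], hnum[hsel], pch = 16)
  graphics::points(as.integer(names(tv)), as.numeric(tv), pch = 1, col = "black")
  graphics::lines(as.integer(names(pv)), as.numeric(pv), col = "firebrick",
                  lwd = 2)
  graphics::legend("topleft", bty = "n", pch = c(16, 1, NA),
                   lty = c(NA, NA, 1), lwd = c(NA, NA, 2),
                   col = c("black", "black", "firebrick"),
                   legend = c("history", "observed future", "forecast"))
  invisible(x)
}

#' Zero-shot forecast of a variable outside the training targets
#'
#' Builds a prompt instructing the fitted backend to forecast a registry
#' variable it was never trained to output, samples `k` completions, decodes
#' them under the ad-hoc schema, and mean-aggregates, with extraction
#' accounting.
#'
#' @param object A `twin_forecaster` with a registry.
#' @param example A `forecast_example`.
#' @param variable Registry variable to forecast.
#' @param offsets Horizon offsets (default: the task horizons).
#' @param k,seed Sampling controls.
#' @return List with `trajectory`, `ensemble` and `n_extracted`/`n_expected`.
#' @export
zero_shot_forecast <- function(object, example, variable, offsets = NULL,
                               k = object$k, seed = NULL) {
  offsets <- offsets %||% object$task$horizons
  registry <- object$registry
  if (is.null(registry)) {
    # ad-hoc registry from what the fitted task and the record know about
    known <- unique(c(object$task$targets, example$history$variable))
    registry <- variable_registry(lapply(known, variable_spec,
                                         role = "covariate",
                                         kind = "categorical"))
  }
  zp <- build_zero_shot_prompt(example, registry, variable, offsets,
                               object$template)
  texts <- generate_text(object$backend, zp$text, k = k, schema = zp$schema,
                         seed = seed)
  decoded <- lapply(texts, decode_forecast, schema = zp$schema)
  vals <- stats::setNames(rep(NA_real_, length(offsets)),
                          as.character(offsets))
  for (o in as.character(offsets)) {
    samples <- unlist(lapply(decoded, function(d) d$values[[variable]][o]))
    samples <- samples[!is.na(samples)]
    if (length(samples)) vals[o] <- mean(samples)
  }
  list(trajectory = stats::setNames(list(vals), variable),
       texts = texts, decoded = decoded,
       n_expected = nrow(zp$schema) * k,
       n_extracted = sum(vapply(decoded, `[[`, integer(1L), "n_extracted")))
}
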