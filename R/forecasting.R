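#' Sample a trajectory ensemble from a backend
#'
#' Draws `k` completions for one encoded example, decodes each through
#' [decode_forecast()], and keeps full parse accounting. All-failed ensembles
#' are valid data, not errors; the raw texts are retained for audit.
#'
#' @param backend A fine-tuned backend.
#' @param encoded An `encoded_example` (prediction schema: full
#'   target x horizon grid).
#' @param k Number of sampled trajectories (the study protocol uses 30, with
#'   the per-time-point mean as the final forecast).
#' @param seed Optional seed.
#' @return An object of class `trajectory_ensemble`: list with `example`,
#'   `schema`, `k`, `texts`, `decoded` (list of `decoded_forecast`), and
#'   `cell_counts` (schema plus `n_parsed` per cell).
#' @export
sample_trajectories <- function(backend, encoded, k = 30L, seed = NULL) {
  stopifnot(inherits(encoded, "encoded_example"), k >= 1L)
  texts <- generate_text(backend, encoded$input, k = k,
                         schema = encoded$schema, seed = seed)
  decoded <- lapply(texts, decode_forecast, schema = encoded$schema)
  counts <- encoded$schema
  counts$n_parsed <- vapply(seq_len(nrow(counts)), function(j) {
    sum(vapply(decoded, function(d) {
      !is.null(d$values[[counts$variable[j]]]) &&
        !is.na(d$values[[counts$variable[j]]][as.character(counts$offset[j])])
    }, logical(1L)))
  }, integer(1L))
  structure(list(example = encoded$example, schema = encoded$schema,
                 k = as.integer(k), texts = texts, decoded = decoded,
                 cell_counts = counts),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  st <- table(factor(vapply(x$decoded, `[[`, character(1L), "status"),
                     levels = c("ok", "partial", "failed")))
  cat(sprintf("<trajectory_ensemble> k=%d (ok %d, partial %d, failed %d), %d cells\n",
              x$k, st[["ok"]], st[["partial"]], st[["failed"]],
              nrow(x$schema)))
  invisible(x)
}

#' Mean-aggregate a trajectory ensemble
#'
#' The final forecast for each (target, offset) cell is the arithmetic mean
#' of the values parsed from the sampled trajectories (partial parses
#' contribute the cells they have). Cells with zero parsed samples fall back
#' to the supplied copy-forward value and are flagged, keeping evaluation
#' denominators comparable across models.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param fallback Optional trajectory (named list variable -> named numeric
#'   by offset) used for all-failed cells, typically
#'   [copy_forward_forecast()].
#' @return The aggregated trajectory, with attribute `"fallback_cells"`
#'   (data.frame of flagged cells; zero rows when none).
#' @export
aggregate_mean <- function(ensemble, fallback = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  schema <- ensemble$schema
  out <- list()
  flagged <- list()
  for (v in unique(schema$variable)) {
    offs <- schema$offset[schema$variable == v]
    vals <- stats::setNames(rep(NA_real_, length(offs)), as.character(offs))
    for (o in as.character(offs)) {
      samples <- unlist(lapply(ensemble$decoded, function(d) d$values[[v]][o]))
      samples <- samples[!is.na(samples)]
      if (length(samples)) {
        vals[o] <- mean(samples)
      } else if (!is.null(fallback) && !is.null(fallback[[v]]) &&
                 !is.na(fallback[[v]][o])) {
        vals[o] <- fallback[[v]][o]
        flagged[[length(flagged) + 1L]] <-
          data.frame(variable = v, offset = as.integer(o))
      }
    }
    out[[v]] <- vals
  }
  attr(out, "fallback_cells") <- if (length(flagged)) do.call(rbind, flagged)
    else data.frame(variable = character(), offset = integer())
  out
}

# Per-example scaled MAE of one trajectory against sparse truth: per target,
# mean |err|/sigma over that target's observed cells, averaged over targets.
example_scaled_mae <- function(values, truth, sigma) {
  per_target <- c()
  for (v in names(truth)) {
    tv <- truth[[v]]
    pv <- values[[v]][names(tv)]
    if (is.null(pv) || anyNA(pv)) return(NA_real_)
    per_target <- c(per_target, mean(abs(tv - pv)) / sigma[[v]])
  }
  if (length(per_target) == 0L) return(NA_real_)
  mean(per_target)
}

#' Oracle best trajectory of an ensemble
#'
#' Selects, with hindsight, the single sampled trajectory with the lowest
#' per-example scaled MAE against the observed truth -- the theoretical lower
#' bound of what a perfect aggregation rule could extract from the ensemble,
#' reported alongside the mean-aggregate error. Only fully parsed samples
#' compete; ties break to the lowest index.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param truth Named list variable -> named numeric by offset (observed
#'   future values).
#' @param sigma Named per-target standard deviations.
#' @return List with `index`, `trajectory`, `scaled_mae`.
#' @export
oracle_best_trajectory <- function(ensemble, truth, sigma) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  ok <- which(vapply(ensemble$decoded, `[[`, character(1L), "status") == "ok")
  if (length(ok) == 0L) stop("no fully parsed sample in ensemble")
  scores <- vapply(ok, function(j) {
    example_scaled_mae(ensemble$decoded[[j]]$values, truth, sigma)
  }, numeric(1L))
  if (all(is.na(scores))) stop("no sample covers the observed truth cells")
  best <- ok[which.min(scores)] # which.min: first minimum, NA dropped
  list(index = best, trajectory = ensemble$decoded[[best]]$values,
       scaled_mae = min(scores, na.rm = TRUE))
}

#' Copy-forward reference forecast
#'
#' The naive baseline: every horizon cell repeats the target's last observed
#' pre-landmark value; targets never observed before the landmark use the
#' training-split median (quantized to reporting precision) and are flagged.
#'
#' @param example A `forecast_example`.
#' @param train_stats Training statistics from [training_statistics()]
#'   (provides the median fallback); optional when every baseline exists.
#' @return Trajectory (named list variable -> named numeric by offset) with
#'   attribute `"imputed"` naming median-imputed targets.
#' @export
copy_forward_forecast <- function(example, train_stats = NULL) {
  stopifnot(inherits(example, "forecast_example"))
  out <- list()
  imputed <- character(0)
  for (v in example$targets) {
    val <- example$baseline[[v]]
    if (is.na(val)) {
      val <- train_stats$median[[v]] %||% NA_real_
      imputed <- c(imputed, v)
    }
    out[[v]] <- stats::setNames(rep(val, length(example$horizons)),
                                as.character(example$horizons))
  }
  attr(out, "imputed") <- imputed
  out
}

#' Training statistics for forecasting and evaluation
#'
#' From the training examples: per-target standard deviation of observed
#' future values (the scaling sigma, computed after outlier filtering
#' upstream) and the per-target median (quantized to the template's reporting
#' precision) used as copy-forward fallback for never-observed baselines.
#' Both pool the observed future target values -- the same multiset a text
#' backend sees in the training target texts.
#'
#' @param examples Training `forecast_example` list.
#' @param precision Reporting precision for the median fallback.
#' @return List with named numeric vectors `sigma` and `median`, and `n_examples`.
#' @export
training_statistics <- function(examples, precision = 1L) {
  pool <- list()
  for (ex in examples) {
    for (v in names(ex$truth)) {
      pool[[v]] <- c(pool[[v]], unname(ex$truth[[v]]))
    }
  }
  list(sigma = vapply(pool, stats::sd, numeric(1L)),
       median = vapply(pool, function(x) {
         round_half_up(stats::median(x), precision)
       }, numeric(1L)),
       n_examples = length(examples))
}

#' Linear reference forecast
#'
#' A simple supervised reference model standing at the opposite end of the
#' spectrum from the naive baseline: for each (target, horizon offset) cell
#' it fits ordinary least squares on training examples with features
#' \[last observed value, time since last observation, static one-hots\]
#' and predicts from the fitted coefficients. Cells that cannot be fit
#' (fewer than 2 training rows, or a degenerate design) fall back to
#' copy-forward and are flagged.
#'
#' @param train_examples Training `forecast_example` list.
#' @param examples Examples to predict.
#' @param statics_vars Static attributes to one-hot encode (default: those
#'   present on the first training example).
#' @param train_stats [training_statistics()] of the training split.
#' @return List of trajectories parallel to `examples`, with attribute
#'   `"fallback_cells"` counting unfittable cells.
#' @export
linear_reference_forecast <- function(train_examples, examples,
                                      statics_vars = NULL,
                                      train_stats = training_statistics(train_examples)) {
  stopifnot(length(train_examples) >= 1L)
  if (is.null(statics_vars)) {
    statics_vars <- names(train_examples[[1L]]$statics)
  }
  targets <- train_examples[[1L]]$targets
  horizons <- train_examples[[1L]]$horizons

  levels_of <- lapply(statics_vars, function(a) {
    sort(unique(vapply(train_examples,
                       function(ex) ex$statics[[a]] %||% NA_character_,
                       character(1L))))
  })
  names(levels_of) <- statics_vars

  feature_row <- function(ex, v) {
    val <- ex$baseline[[v]]
    if (is.na(val)) val <- train_stats$median[[v]] %||% 0
    hist <- ex$history
    hnum <- obs_numeric(hist)
    sel <- which(hist$variable == v & !is.na(hnum))
    gap <- if (length(sel)) -max(hist$time[sel]) else
      max(1, -min(c(hist$time, 0))) + 1
    feats <- c(1, val, gap)
    for (a in statics_vars) {
      lv <- levels_of[[a]]
      if (length(lv) < 2L) next
      x <- ex$statics[[a]] %||% NA_character_
      feats <- c(feats, as.numeric(lv[-1L] == x)) # baseline = first level
    }
    feats
  }

  fits <- list()
  for (v in targets) {
    X <- t(vapply(train_examples, feature_row, v = v,
                  numeric(length(feature_row(train_examples[[1L]], v)))))
    for (o in horizons) {
      y <- vapply(train_examples, function(ex) {
        tv <- ex$truth[[v]]
        if (is.null(tv)) NA_real_ else unname(tv[as.character(o)])
      }, numeric(1L))
      keep <- !is.na(y)
      key <- paste(v, o)
      if (sum(keep) < 2L) { fits[[key]] <- NULL; next }
      fit <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])
      if (fit$rank < ncol(X)) {
        # drop aliased columns instead of giving up
        used <- !is.na(fit$coefficients)
        if (sum(used) == 0L) { fits[[key]] <- NULL; next }
        fits[[key]] <- list(coef = fit$coefficients[used], cols = which(used))
      } else {
        fits[[key]] <- list(coef = fit$coefficients, cols = seq_len(ncol(X)))
      }
    }
  }

  n_fallback <- 0L
  out <- lapply(examples, function(ex) {
    cf <- copy_forward_forecast(ex, train_stats)
    traj <- list()
    for (v in targets) {
      feats <- feature_row(ex, v)
      vals <- stats::setNames(rep(NA_real_, length(horizons)),
                              as.character(horizons))
      for (o in horizons) {
        fit <- fits[[paste(v, o)]]
        if (is.null(fit)) {
          vals[as.character(o)] <- cf[[v]][as.character(o)]
          n_fallback <<- n_fallback + 1L
        } else {
          vals[as.character(o)] <- sum(fit$coef * feats[fit$cols])
        }
      }
      traj[[v]] <- vals
    }
    traj
  })
  attr(out, "fallback_cells") <- n_fallback
  out
}
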