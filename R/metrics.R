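#' Metric configuration
#'
#' Records the constants every evaluation needs: the per-target standard
#' deviation used for error scaling (computed on the training split after
#' outlier filtering), the registry holding clinical reference ranges, and
#' the trend lookback window.
#'
#' @param sigma Named numeric vector of per-target standard deviations
#'   (strictly positive for every scored target).
#' @param registry Optional [variable_registry()] providing reference ranges
#'   (possibly sex-conditional) for the classification metrics.
#' @param trend_window Lookback window `s`, in task time units (e.g. 3 for a
#'   3-week trend on weekly bins).
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(sigma, registry = NULL, trend_window = 3L) {
  stopifnot(is.numeric(sigma), !is.null(names(sigma)), all(sigma > 0),
            trend_window > 0)
  structure(list(sigma = sigma, registry = registry,
                 trend_window = as.integer(trend_window)),
            class = "metric_config")
}

#' Assemble forecasts and truths into a long evaluation panel
#'
#' One row per scored cell: a (patient sample, target, horizon offset) with
#' observed truth and (where available) the model's prediction. The patient
#' sample (one landmark example) is the nesting unit of all error metrics.
#'
#' @param forecasts List of trajectories parallel to `examples`: each a named
#'   list `variable -> named numeric vector keyed by offset` (as returned by
#'   [aggregate_mean()] or the reference forecasters).
#' @param examples List of `forecast_example` objects.
#' @return data.frame with columns `unit` (example id), `patient_id`,
#'   `variable`, `offset`, `truth`, `pred`, `v0` (baseline value, `NA` when
#'   never observed pre-landmark).
#' @export
forecast_panel <- function(forecasts, examples) {
  stopifnot(length(forecasts) == length(examples))
  rows <- vector("list", length(examples))
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    fc <- forecasts[[i]]
    if (inherits(fc, "decoded_forecast")) fc <- fc$values
    unit <- paste0(ex$patient_id, "@", ex$t0)
    part <- lapply(names(ex$truth), function(v) {
      tv <- ex$truth[[v]]
      pred <- fc[[v]][names(tv)]
      data.frame(unit = unit, patient_id = ex$patient_id, variable = v,
                 offset = as.integer(names(tv)), truth = as.numeric(tv),
                 pred = if (is.null(pred)) NA_real_ else as.numeric(pred),
                 v0 = unname(ex$baseline[[v]]),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, part)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out %||% data.frame(unit = character(), patient_id = character(),
                      variable = character(), offset = integer(),
                      truth = numeric(), pred = numeric(), v0 = numeric())
}

# Patient-nested mean: average within each unit first, then across units.
nested_mean <- function(values, unit) {
  if (length(values) == 0L) return(NA_real_)
  mean(tapply(values, unit, mean))
}

#' Patient-nested forecast error metrics
#'
#' Computes, per target variable, the four regression error metrics with
#' patient-nested averaging: the inner mean runs over the `T_i` observed
#' future points of one patient sample, the outer mean over samples.
#' \itemize{
#'   \item MAE: nested mean of `|truth - pred|`.
#'   \item scaled MAE: `MAE / sigma` (sigma = training-split standard
#'     deviation after outlier filtering).
#'   \item MASE: nested MAE divided by the nested error of always predicting
#'     the baseline value `v0`; samples with no pre-landmark baseline or a
#'     zero baseline-error denominator are excluded from both numerator and
#'     denominator (count reported).
#'   \item SMAPE: `200/n` times the nested mean of
#'     `|truth - pred| / (|truth| + |pred|)`, the term set to zero when the
#'     denominator is zero.
#' }
#'
#' @param panel Evaluation panel from [forecast_panel()] (rows with `NA`
#'   predictions are not scoreable and are dropped with a count).
#' @param sigma Named per-target standard deviations.
#' @return data.frame, one row per target: `MAE`, `scaled_MAE`, `MASE`,
#'   `SMAPE`, `n_units`, `n_points`, `mase_excluded` (units), `unscored`
#'   (dropped NA-prediction rows).
#' @export
forecast_errors <- function(panel, sigma) {
  out <- lapply(sort(unique(panel$variable)), function(v) {
    rows <- panel[panel$variable == v, , drop = FALSE]
    unscored <- sum(is.na(rows$pred))
    rows <- rows[!is.na(rows$pred), , drop = FALSE]
    if (nrow(rows) == 0L) {
      return(data.frame(variable = v, MAE = NA_real_, scaled_MAE = NA_real_,
                        MASE = NA_real_, SMAPE = NA_real_, n_units = 0L,
                        n_points = 0L, mase_excluded = 0L,
                        unscored = unscored))
    }
    abs_err <- abs(rows$truth - rows$pred)
    mae <- nested_mean(abs_err, rows$unit)

    s <- sigma[[v]]
    if (is.null(s) || !is.finite(s) || s <= 0) {
      stop("positive sigma required for target ", v)
    }

    # MASE: units with a real baseline and nonzero baseline error
    base_err <- abs(rows$truth - rows$v0)
    unit_has_v0 <- tapply(!is.na(rows$v0), rows$unit, all)
    unit_base <- tapply(base_err, rows$unit, mean)
    eligible <- names(unit_has_v0)[unit_has_v0 & !is.na(unit_base) &
                                     unit_base > 0]
    mase <- if (length(eligible)) {
      keep <- rows$unit %in% eligible
      nested_mean(abs_err[keep], rows$unit[keep]) /
        nested_mean(base_err[keep], rows$unit[keep])
    } else NA_real_

    denom <- abs(rows$truth) + abs(rows$pred)
    term <- ifelse(denom == 0, 0, abs_err / denom)
    smape <- 200 * nested_mean(term, rows$unit)

    data.frame(variable = v, MAE = mae, scaled_MAE = mae / s, MASE = mase,
               SMAPE = smape, n_units = length(unique(rows$unit)),
               n_points = nrow(rows),
               mase_excluded = length(unique(rows$unit)) - length(eligible),
               unscored = unscored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Weighted Spearman correlation between forecasts and truth
#'
#' Ranks are computed over the pooled observed values of one target (average
#' ranks for ties), separately for truths and predictions, then combined in a
#' weighted Pearson correlation with per-cell weight `1/(n * T_i)`, so every
#' patient sample contributes equally regardless of how many future points it
#' has.
#'
#' @inheritParams forecast_errors
#' @return data.frame with columns `variable`, `spearman_rho` (`NA` when
#'   fewer than 2 scored points or zero rank variance).
#' @export
spearman_weighted <- function(panel) {
  out <- lapply(sort(unique(panel$variable)), function(v) {
    rows <- panel[panel$variable == v & !is.na(panel$pred), , drop = FALSE]
    rho <- NA_real_
    if (nrow(rows) >= 2L) {
      rt <- rank(rows$truth, ties.method = "average")
      rp <- rank(rows$pred, ties.method = "average")
      t_i <- table(rows$unit)
      w <- 1 / (length(t_i) * as.numeric(t_i[rows$unit]))
      mt <- sum(w * rt); mp <- sum(w * rp) # weights sum to 1
      st <- sum(w * (rt - mt)^2); sp <- sum(w * (rp - mp)^2)
      if (st > 0 && sp > 0) {
        rho <- sum(w * (rt - mt) * (rp - mp)) / sqrt(st * sp)
      }
    }
    data.frame(variable = v, spearman_rho = rho, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Label values against a clinical reference interval
#'
#' `"low"` below the interval, `"high"` above, `"normal"` inside; equality
#' with either boundary counts as normal (closed-interval convention).
#'
#' @param values Numeric vector.
#' @param range Numeric `c(min, max)`, or a 2-column matrix with one row per
#'   value (for e.g. sex-specific ranges).
#' @return Character vector of labels (`NA` where the range is missing).
#' @export
label_reference <- function(values, range) {
  if (is.null(dim(range))) {
    range <- matrix(range, nrow = length(values), ncol = 2L, byrow = TRUE)
  }
  out <- rep(NA_character_, length(values))
  ok <- !is.na(values) & !is.na(range[, 1L]) & !is.na(range[, 2L])
  out[ok] <- ifelse(values[ok] < range[ok, 1L], "low",
                    ifelse(values[ok] > range[ok, 2L], "high", "normal"))
  out
}

# Mann-Whitney AUC with 0.5 credit for score ties; NA unless both classes
# are represented.
auc_mw <- function(scores, positive) {
  ok <- !is.na(scores) & !is.na(positive)
  scores <- scores[ok]; positive <- as.logical(positive[ok])
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Reference-range classification AUCs
#'
#' Derives the three binary tasks low/not-low, high/not-high and
#' normal/not-normal from the observed truth labels, scores each with a
#' Mann-Whitney ROC AUC using signed threshold distances of the predicted
#' value (`v_min - pred` for low, `pred - v_max` for high,
#' `min(pred - v_min, v_max - pred)` for normal), and aggregates them into a
#' class-count-weighted AUC accounting for class imbalance. Tasks without
#' both a positive and a negative example are reported missing and drop out
#' of the weighted mean.
#'
#' @param pred Predicted values.
#' @param truth Observed values.
#' @param range Reference interval as in [label_reference()].
#' @return One-row data.frame: `AUC_low`, `AUC_high`, `AUC_normal`,
#'   `AUC_weighted`, class counts `n_low`, `n_normal`, `n_high`.
#' @export
auc_reference <- function(pred, truth, range) {
  if (is.null(dim(range))) {
    range <- matrix(range, nrow = length(pred), ncol = 2L, byrow = TRUE)
  }
  labels <- label_reference(truth, range)
  ok <- !is.na(labels) & !is.na(pred)
  labels <- labels[ok]; pred <- pred[ok]; range <- range[ok, , drop = FALSE]
  counts <- c(low = sum(labels == "low"), normal = sum(labels == "normal"),
              high = sum(labels == "high"))
  aucs <- c(
    low = auc_mw(range[, 1L] - pred, labels == "low"),
    normal = auc_mw(pmin(pred - range[, 1L], range[, 2L] - pred),
                    labels == "normal"),
    high = auc_mw(pred - range[, 2L], labels == "high"))
  avail <- !is.na(aucs) & counts > 0
  weighted <- if (any(avail)) {
    sum(aucs[avail] * counts[avail]) / sum(counts[avail])
  } else NA_real_
  data.frame(AUC_low = aucs[["low"]], AUC_high = aucs[["high"]],
             AUC_normal = aucs[["normal"]], AUC_weighted = weighted,
             n_low = counts[["low"]], n_normal = counts[["normal"]],
             n_high = counts[["high"]])
}

#' Trend labels over a lookback window
#'
#' A trajectory point at time `t` is labeled `"decreasing"` when every
#' consecutive change over the preceding lookback window of length `s` is
#' strictly downward, i.e. `v[k+1] < v[k]` for all `k` in `t-s, ..., t-1`
#' on the time grid; `"increasing"` symmetrically; `"neither"` when the
#' window is complete but not consistent. Points with `time < s`, or whose
#' window has a missing grid point, are `"excluded"`.
#'
#' @param values Numeric trajectory values.
#' @param times Integer times (task time units) parallel to `values`.
#' @param s Lookback window length in time units.
#' @return Character vector of labels parallel to `values`.
#' @export
trend_labels <- function(values, times, s) {
  stopifnot(length(values) == length(times), s > 0)
  lookup <- stats::setNames(values, as.character(times))
  vapply(seq_along(times), function(j) {
    t <- times[j]
    if (t < s) return("excluded")
    grid <- as.character(seq(t - s, t))
    win <- lookup[grid]
    if (anyNA(win)) return("excluded")
    d <- diff(win)
    if (all(d < 0)) "decreasing" else if (all(d > 0)) "increasing" else "neither"
  }, character(1L))
}

# Worst-case consecutive margin over the window: positive exactly when the
# strict trend label holds. direction = +1 for decreasing, -1 for increasing.
trend_scores <- function(values, times, s, direction) {
  lookup <- stats::setNames(values, as.character(times))
  vapply(seq_along(times), function(j) {
    t <- times[j]
    if (t < s) return(NA_real_)
    win <- lookup[as.character(seq(t - s, t))]
    if (anyNA(win)) return(NA_real_)
    min(direction * -diff(win)) # min over pairs of direction*(v_k - v_{k+1})
  }, numeric(1L))
}

#' Trend classification AUCs
#'
#' Evaluates whether forecasts reproduce sustained monotone trends: truth
#' labels come from [trend_labels()] applied to the observed trajectory, the
#' ROC score of a point is the worst-case consecutive margin of the
#' *predicted* trajectory over the same window (positive exactly when the
#' prediction itself satisfies the strict trend), and the two binary tasks
#' decreasing/not-decreasing and increasing/not-increasing are scored by
#' Mann-Whitney AUC. Points excluded on either side (incomplete window or
#' `time < s`) are dropped with a count.
#'
#' @param truth_trajs,pred_trajs Lists of named numeric vectors (names are
#'   integer times), one pair per patient sample. Including the baseline
#'   value at time 0 lets early horizon points have a complete window.
#' @param s Lookback window length.
#' @return One-row data.frame: `AUC_trend_down`, `AUC_trend_up`,
#'   `n_points`, `n_excluded`.
#' @export
auc_trend <- function(truth_trajs, pred_trajs, s) {
  stopifnot(length(truth_trajs) == length(pred_trajs))
  lab <- character(0); sc_dn <- numeric(0); sc_up <- numeric(0)
  n_excl <- 0L
  for (i in seq_along(truth_trajs)) {
    tv <- truth_trajs[[i]]; pv <- pred_trajs[[i]]
    tt <- as.integer(names(tv)); pt <- as.integer(names(pv))
    lt <- trend_labels(as.numeric(tv), tt, s)
    # score only horizon points (time > 0) labeled on the truth side
    horizon <- tt > 0
    dn <- trend_scores(as.numeric(pv), pt, s, +1)[match(tt, pt)]
    up <- trend_scores(as.numeric(pv), pt, s, -1)[match(tt, pt)]
    usable <- horizon & lt != "excluded" & !is.na(dn) & !is.na(up)
    n_excl <- n_excl + sum(horizon) - sum(usable)
    lab <- c(lab, lt[usable])
    sc_dn <- c(sc_dn, dn[usable])
    sc_up <- c(sc_up, up[usable])
  }
  data.frame(AUC_trend_down = auc_mw(sc_dn, lab == "decreasing"),
             AUC_trend_up = auc_mw(sc_up, lab == "increasing"),
             n_points = length(lab), n_excluded = n_excl)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Sup-norm distance between the empirical cumulative distribution functions
#' of the pooled predicted and pooled observed values (well defined with
#' ties).
#'
#' @param pred,truth Numeric pools (both nonempty).
#' @return The statistic `D` in `[0, 1]`, or `NA` for an empty pool.
#' @export
ks_statistic <- function(pred, truth) {
  pred <- pred[!is.na(pred)]; truth <- truth[!is.na(truth)]
  if (length(pred) == 0L || length(truth) == 0L) return(NA_real_)
  grid <- sort(unique(c(pred, truth)))
  f1 <- vapply(grid, function(g) mean(pred <= g), numeric(1L))
  f2 <- vapply(grid, function(g) mean(truth <= g), numeric(1L))
  max(abs(f1 - f2))
}

#' Cross-variable correlation preservation
#'
#' For every pair of targets, computes the Pearson correlation across the
#' pooled (patient sample, offset) cells where both variables have observed
#' truth -- once on the truths and once on the predictions -- and reports the
#' squared Pearson correlation between the two resulting vectors of pairwise
#' correlations. A high value means the forecasts reproduce the cohort's
#' inter-variable correlation structure.
#'
#' @inheritParams forecast_errors
#' @param min_cells Minimum co-observed cells for a pair to enter (default 3).
#' @return A list: `r_squared` (`NA` when fewer than 2 valid pairs),
#'   `pairs` data.frame with per-pair truth/prediction correlations.
#' @export
correlation_preservation <- function(panel, min_cells = 3L) {
  targets <- sort(unique(panel$variable))
  key <- paste(panel$unit, panel$offset, sep = "\r")
  rows <- list()
  for (a in seq_along(targets)) {
    for (b in seq_len(a - 1L)) {
      ia <- which(panel$variable == targets[a] & !is.na(panel$pred))
      ib <- which(panel$variable == targets[b] & !is.na(panel$pred))
      common <- intersect(key[ia], key[ib])
      if (length(common) < min_cells) next
      ta <- panel$truth[ia][match(common, key[ia])]
      tb <- panel$truth[ib][match(common, key[ib])]
      pa <- panel$pred[ia][match(common, key[ia])]
      pb <- panel$pred[ib][match(common, key[ib])]
      ct <- if (stats::sd(ta) > 0 && stats::sd(tb) > 0) stats::cor(ta, tb) else NA_real_
      cp <- if (stats::sd(pa) > 0 && stats::sd(pb) > 0) stats::cor(pa, pb) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        var_a = targets[a], var_b = targets[b], truth_cor = ct,
        pred_cor = cp, n_cells = length(common), stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows) %||%
    data.frame(var_a = character(), var_b = character(),
               truth_cor = numeric(), pred_cor = numeric(),
               n_cells = integer())
  valid <- pairs[!is.na(pairs$truth_cor) & !is.na(pairs$pred_cor), ,
                 drop = FALSE]
  r2 <- if (nrow(valid) >= 2L && stats::sd(valid$truth_cor) > 0 &&
            stats::sd(valid$pred_cor) > 0) {
    stats::cor(valid$truth_cor, valid$pred_cor)^2
  } else NA_real_
  list(r_squared = r2, pairs = pairs)
}

#' Full metric report for a set of forecasts
#'
#' Runs the complete evaluation suite over aligned forecasts and examples:
#' per-target regression errors ([forecast_errors()]), weighted Spearman
#' correlation, reference-range classification AUCs (resolving
#' sex-conditional ranges per patient), trend AUCs with the configured
#' lookback window (baseline value prepended at time 0 so early horizons
#' have complete windows), per-target KS distances, and the pooled
#' correlation-preservation R-squared. The constants used (sigma, window,
#' ranges) are recorded in the report.
#'
#' @param forecasts List of trajectories parallel to `examples`.
#' @param examples List of `forecast_example` objects.
#' @param config A [metric_config()].
#' @return An object of class `metric_report`.
#' @export
evaluate_forecasts <- function(forecasts, examples, config) {
  stopifnot(inherits(config, "metric_config"))
  panel <- forecast_panel(forecasts, examples)
  errors <- forecast_errors(panel, config$sigma)
  spearman <- spearman_weighted(panel)

  targets <- sort(unique(panel$variable))
  classification <- NULL
  if (!is.null(config$registry)) {
    cls <- lapply(targets, function(v) {
      if (is.null(config$registry[[v]]) ||
          is.null(config$registry[[v]]$reference_range)) return(NULL)
      rows <- panel[panel$variable == v & !is.na(panel$pred), , drop = FALSE]
      if (nrow(rows) == 0L) return(NULL)
      ranges <- t(vapply(seq_len(nrow(rows)), function(j) {
        ex_statics <- statics_by_patient(examples)[[rows$patient_id[j]]]
        r <- reference_range_for(config$registry, v, ex_statics)
        r %||% c(NA_real_, NA_real_)
      }, numeric(2L)))
      cbind(data.frame(variable = v, stringsAsFactors = FALSE),
            auc_reference(rows$pred, rows$truth, ranges))
    })
    cls <- cls[!vapply(cls, is.null, logical(1L))]
    classification <- if (length(cls)) do.call(rbind, cls)
  }

  trend <- lapply(targets, function(v) {
    tt <- list(); pp <- list()
    for (ex_i in seq_along(examples)) {
      ex <- examples[[ex_i]]
      tv <- ex$truth[[v]]
      if (is.null(tv)) next
      fc <- forecasts[[ex_i]]
      if (inherits(fc, "decoded_forecast")) fc <- fc$values
      pv <- fc[[v]]
      if (is.null(pv)) next
      v0 <- ex$baseline[[v]]
      if (!is.na(v0)) { # anchor both trajectories at the landmark
        tv <- c(stats::setNames(v0, "0"), tv)
        pv <- c(stats::setNames(v0, "0"), pv)
      }
      tt[[length(tt) + 1L]] <- tv
      pp[[length(pp) + 1L]] <- pv
    }
    if (length(tt) == 0L) return(NULL)
    cbind(data.frame(variable = v, stringsAsFactors = FALSE),
          auc_trend(tt, pp, config$trend_window))
  })
  trend <- trend[!vapply(trend, is.null, logical(1L))]
  trend <- if (length(trend)) do.call(rbind, trend)

  ks <- vapply(targets, function(v) {
    rows <- panel[panel$variable == v, , drop = FALSE]
    ks_statistic(rows$pred, rows$truth)
  }, numeric(1L))

  corr <- correlation_preservation(panel)

  structure(list(errors = errors, spearman = spearman,
                 classification = classification, trend = trend,
                 ks = data.frame(variable = targets, KS_D = unname(ks)),
                 correlation_r2 = corr$r_squared,
                 correlation_pairs = corr$pairs,
                 constants = list(sigma = config$sigma,
                                  trend_window = config$trend_window),
                 n_examples = length(examples),
                 panel = panel),
            class = "metric_report")
}

statics_by_patient <- function(examples) {
  out <- list()
  for (ex in examples) out[[ex$patient_id]] <- ex$statics
  out
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("Forecast evaluation over", x$n_examples, "patient samples\n\n")
  tab <- merge(x$errors, x$spearman, by = "variable")
  print(format(tab[, c("variable", "MAE", "scaled_MAE", "MASE", "SMAPE",
                       "spearman_rho")], digits = digits), row.names = FALSE)
  if (!is.null(x$classification)) {
    cat("\nReference-range classification (ROC AUC):\n")
    print(format(x$classification, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$trend)) {
    cat("\nTrend classification (ROC AUC, lookback s =",
        x$constants$trend_window, "):\n")
    print(format(x$trend, digits = digits), row.names = FALSE)
  }
  cat("\nDistribution distance (KS):\n")
  print(format(x$ks, digits = digits), row.names = FALSE)
  cat("\nCorrelation preservation R^2:",
      format(x$correlation_r2, digits = digits), "\n")
  invisible(x)
}

#' Serialize a metric report
#'
#' @param report A `metric_report`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_metric_report <- function(report, path) {
  out <- report[c("errors", "spearman", "classification", "trend", "ks",
                  "correlation_r2", "constants", "n_examples")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}
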