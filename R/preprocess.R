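#' Forecasting task configuration
#'
#' Fixes the temporal resolution and the prediction problem: the bin width
#' that maps raw timestamps to integer time steps, the forecast horizon grid,
#' the target variables, and the landmarking policy that splits each patient's
#' record into history (input) and future (output).
#'
#' Landmark policies:
#' \describe{
#'   \item{`therapy_start`}{one forecast example per observed event of
#'     `landmark_variable` (e.g. the start of each line of therapy); history is
#'     all data up to that event.}
#'   \item{`fixed_history`}{a single example with the landmark placed
#'     `history_bins` bins after the patient's first observation (e.g. the
#'     first 24 h in an ICU stay).}
#'   \item{`baseline_only`}{a single example landmarked at the patient's first
#'     observed bin (only baseline measurements as history).}
#' }
#'
#' @param bin_width Width of one time bin in raw time units (e.g. 7 for
#'   weekly bins over day-stamped data, 1 for hourly bins over hour stamps).
#' @param horizons Strictly increasing positive integer bin offsets to
#'   forecast, e.g. `1:13` for thirteen weekly values.
#' @param targets Character vector of target variable names (nonempty).
#' @param landmark_policy One of `"therapy_start"`, `"fixed_history"`,
#'   `"baseline_only"`.
#' @param landmark_variable Event variable anchoring `therapy_start`
#'   landmarks.
#' @param history_bins History length for `fixed_history` (in bins).
#' @param unit_label Human label for one bin ("week", "hour", "month"), used
#'   by the text encoder.
#' @return An object of class `task_config`.
#' @export
task_config <- function(bin_width, horizons, targets,
                        landmark_policy = c("therapy_start", "fixed_history",
                                            "baseline_only"),
                        landmark_variable = "therapy",
                        history_bins = NULL,
                        unit_label = "week") {
  landmark_policy <- match.arg(landmark_policy)
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0)
  horizons <- as.integer(horizons)
  if (length(horizons) == 0L || any(horizons <= 0L) ||
      any(diff(horizons) <= 0L)) {
    stop("horizons must be strictly increasing positive integers")
  }
  if (length(targets) == 0L) stop("targets must be nonempty")
  if (landmark_policy == "fixed_history" &&
      (is.null(history_bins) || history_bins <= 0)) {
    stop("fixed_history policy requires a positive history_bins")
  }
  structure(list(bin_width = bin_width, horizons = horizons,
                 targets = as.character(targets),
                 landmark_policy = landmark_policy,
                 landmark_variable = landmark_variable,
                 history_bins = if (is.null(history_bins)) NULL else as.integer(history_bins),
                 unit_label = unit_label),
            class = "task_config")
}

#' Aggregate observations into time bins by last observed value
#'
#' Maps each raw timestamp to the integer bin `floor(time / bin_width)` and,
#' where a (patient, variable) pair has several observations in one bin, keeps
#' only the last observed value (latest raw timestamp; later input row wins
#' exact ties). Bins without any observation stay absent -- no imputation.
#' Idempotent: binning an already-binned cohort is a no-op.
#'
#' @param x A `twin_cohort` with raw timestamps.
#' @param bin_width Bin width in raw time units.
#' @return A binned `twin_cohort` (integer `time` = bin offsets).
#' @export
bin_last_observed <- function(x, bin_width) {
  stopifnot(inherits(x, "twin_cohort"))
  obs <- x$observations
  if (x$binned) return(x)
  if (nrow(obs) == 0L) return(cohort(obs, x$statics, binned = TRUE))
  bin <- floor(obs$time / bin_width)
  # stable order: within (patient, variable, bin) the latest raw time, then
  # latest original row, survives
  ord <- order(obs$patient_id, obs$variable, bin, obs$time, seq_len(nrow(obs)))
  obs <- obs[ord, , drop = FALSE]
  bin <- bin[ord]
  key <- paste(obs$patient_id, obs$variable, bin, sep = "\r")
  keep <- !duplicated(key, fromLast = TRUE)
  obs <- obs[keep, , drop = FALSE]
  obs$time <- as.numeric(bin[keep])
  cohort(obs, x$statics, binned = TRUE)
}

#' Two-step outlier filtering of target values
#'
#' Step 1 computes, per target variable, the mean and standard deviation of
#' the *training-split* values and removes (from every split) values outside
#' mean +/- 3 sd. Step 2 recomputes mean and sd on the training survivors and
#' clips all remaining values of that variable into the recomputed
#' mean +/- 3 sd band. When the recomputed sd is zero the variable is left
#' unclipped and flagged as degenerate. The resulting bounds are recorded so
#' the identical rule is applied to every split.
#'
#' @param x A `twin_cohort`.
#' @param targets Target variable names to filter.
#' @param train_ids Patient ids of the training split (statistics source);
#'   default: all patients.
#' @return A list with elements `cohort` (filtered + clipped) and `bounds`
#'   (data.frame, one row per target: step-1/step-2 statistics and bounds,
#'   removal count, degeneracy flag).
#' @export
filter_outliers <- function(x, targets, train_ids = NULL) {
  stopifnot(inherits(x, "twin_cohort"))
  obs <- x$observations
  train_ids <- train_ids %||% cohort_patients(x)
  num <- obs_numeric(obs)

  rows <- lapply(targets, function(v) {
    tr <- which(obs$variable == v & obs$patient_id %in% train_ids & !is.na(num))
    if (length(tr) == 0L) stop("no training values for target ", v)
    m1 <- mean(num[tr]); s1 <- stats::sd(num[tr])
    if (is.na(s1)) s1 <- 0
    lo1 <- m1 - 3 * s1; hi1 <- m1 + 3 * s1
    surv <- tr[num[tr] >= lo1 & num[tr] <= hi1]
    m2 <- mean(num[surv]); s2 <- stats::sd(num[surv])
    if (is.na(s2)) s2 <- 0
    data.frame(variable = v, mean1 = m1, sd1 = s1, lo1 = lo1, hi1 = hi1,
               mean2 = m2, sd2 = s2,
               lo2 = if (s2 > 0) m2 - 3 * s2 else NA_real_,
               hi2 = if (s2 > 0) m2 + 3 * s2 else NA_real_,
               degenerate = s2 == 0, stringsAsFactors = FALSE)
  })
  bounds <- do.call(rbind, rows)

  drop <- logical(nrow(obs))
  removed <- integer(nrow(bounds))
  for (i in seq_len(nrow(bounds))) {
    b <- bounds[i, ]
    sel <- which(obs$variable == b$variable & !is.na(num))
    out1 <- sel[num[sel] < b$lo1 | num[sel] > b$hi1]
    drop[out1] <- TRUE
    removed[i] <- length(out1)
    if (!b$degenerate) {
      keep <- setdiff(sel, out1)
      clipped <- pmin(pmax(num[keep], b$lo2), b$hi2)
      changed <- clipped != num[keep]
      if (any(changed)) {
        obs$value[keep[changed]] <- as.character(clipped[changed])
      }
    }
  }
  bounds$n_removed_step1 <- removed
  list(cohort = cohort(obs[!drop, , drop = FALSE], x$statics, binned = x$binned),
       bounds = bounds)
}

#' Patient-level train/validation/test split
#'
#' Assigns whole patients to disjoint splits, optionally stratified by static
#' attributes so each stratum's split proportions match the requested
#' fractions (largest-remainder allocation within stratum). Strata smaller
#' than the number of splits fall back to unstratified random assignment with
#' a warning. Deterministic given `seed`.
#'
#' @param x A `twin_cohort` (or character vector of patient ids).
#' @param fractions Named numeric vector summing to 1, e.g.
#'   `c(train = .8, validation = .1, test = .1)`.
#' @param strata Optional character vector of static attribute names.
#' @param seed Integer seed.
#' @return Named list of disjoint patient-id character vectors covering the
#'   cohort.
#' @export
split_patients <- function(x, fractions = c(train = 0.8, validation = 0.1,
                                            test = 0.1),
                           strata = NULL, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, !is.null(names(fractions)))
  ids <- if (inherits(x, "twin_cohort")) cohort_patients(x) else sort(unique(x))
  n_split <- length(fractions)

  stratum_of <- rep("(all)", length(ids))
  if (!is.null(strata) && inherits(x, "twin_cohort")) {
    key <- vapply(ids, function(id) {
      s <- patient_statics(x, id)
      miss <- setdiff(strata, names(s))
      if (length(miss)) stop("stratum attribute missing for patient ", id, ": ",
                             paste(miss, collapse = ", "))
      paste(s[strata], collapse = "|")
    }, character(1L))
    stratum_of <- key
  }

  assign_frac <- function(n) {
    # largest-remainder apportionment of n patients to the fractions
    raw <- fractions * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    base
  }

  out <- stats::setNames(vector("list", n_split), names(fractions))
  with_seed(seed, {
    small <- character(0)
    pool_small <- character(0)
    for (st in sort(unique(stratum_of))) {
      members <- ids[stratum_of == st]
      if (length(members) < n_split && st != "(all)") {
        small <- c(small, st)
        pool_small <- c(pool_small, members)
        next
      }
      members <- sample(members)
      sizes <- assign_frac(length(members))
      idx <- 1L
      for (j in seq_len(n_split)) {
        take <- seq_len(sizes[j]) + idx - 1L
        out[[j]] <- c(out[[j]], if (sizes[j] > 0) members[take] else character(0))
        idx <- idx + sizes[j]
      }
    }
    if (length(small)) {
      warning("strata smaller than number of splits, assigned randomly: ",
              paste(small, collapse = ", "))
      members <- sample(pool_small)
      sizes <- assign_frac(length(members))
      idx <- 1L
      for (j in seq_len(n_split)) {
        take <- seq_len(sizes[j]) + idx - 1L
        out[[j]] <- c(out[[j]], if (sizes[j] > 0) members[take] else character(0))
        idx <- idx + sizes[j]
      }
    }
  })
  lapply(out, function(v) sort(unname(v %||% character(0))))
}

#' Construct landmark forecast examples
#'
#' Splits each patient's binned record into history (observations at or before
#' the landmark, re-indexed so the landmark is bin 0) and sparse future truth
#' (observed target values at the configured horizon offsets). Examples with
#' no observed future value for any target are dropped, with accounting.
#'
#' @param x A binned `twin_cohort`.
#' @param task A [task_config()].
#' @return A list of `forecast_example` objects with attribute `dropped`
#'   (data.frame of patient/landmark pairs dropped for lack of future truth).
#' @export
make_examples <- function(x, task) {
  stopifnot(inherits(x, "twin_cohort"), inherits(task, "task_config"))
  if (!x$binned) stop("cohort must be binned to task time units first")
  obs <- x$observations
  examples <- list()
  dropped <- list()
  for (id in cohort_patients(x)) {
    pobs <- obs[obs$patient_id == id, , drop = FALSE]
    if (nrow(pobs) == 0L) next
    landmarks <- switch(task$landmark_policy,
      therapy_start = sort(unique(pobs$time[pobs$variable == task$landmark_variable])),
      fixed_history = min(pobs$time) + task$history_bins,
      baseline_only = min(pobs$time)
    )
    if (length(landmarks) == 0L) next
    statics <- patient_statics(x, id)
    for (t0 in landmarks) {
      ex <- build_example(pobs, statics, id, t0, task)
      if (is.null(ex)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(patient_id = id, t0 = t0, stringsAsFactors = FALSE)
      } else {
        examples[[length(examples) + 1L]] <- ex
      }
    }
  }
  attr(examples, "dropped") <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else {
    data.frame(patient_id = character(), t0 = numeric())
  }
  examples
}

build_example <- function(pobs, statics, id, t0, task) {
  hist <- pobs[pobs$time <= t0, , drop = FALSE]
  hist$time <- hist$time - t0
  num <- obs_numeric(pobs)
  truth <- list()
  for (v in task$targets) {
    sel <- which(pobs$variable == v & (pobs$time - t0) %in% task$horizons &
                 !is.na(num))
    if (length(sel)) {
      tv <- stats::setNames(num[sel], as.character(pobs$time[sel] - t0))
      truth[[v]] <- tv[order(as.integer(names(tv)))]
    }
  }
  if (length(truth) == 0L) return(NULL)
  baseline <- stats::setNames(rep(NA_real_, length(task$targets)), task$targets)
  hnum <- obs_numeric(hist)
  for (v in task$targets) {
    sel <- which(hist$variable == v & !is.na(hnum))
    if (length(sel)) baseline[[v]] <- hnum[sel[which.max(hist$time[sel])]]
  }
  forecast_example(patient_id = id, t0 = t0, history = hist,
                   statics = statics, baseline = baseline, truth = truth,
                   task = task)
}

#' @rdname make_examples
#' @param patient_id,t0,history,statics,baseline,truth,task Fields of the
#'   example; see Details.
#' @details A `forecast_example` holds: `patient_id`; the landmark bin `t0` on
#'   the patient's original time axis; `history` (observations re-indexed so
#'   the landmark is time 0; all times <= 0); `statics` (named character
#'   vector); `baseline` (per-target last observed value at or before the
#'   landmark, `NA` when never observed); and `truth` (per-target named
#'   numeric vector of observed future values keyed by horizon offset).
#' @export
forecast_example <- function(patient_id, t0, history, statics, baseline,
                             truth, task) {
  if (nrow(history) && any(history$time > 0)) {
    stop("history observation after the landmark")
  }
  for (v in names(truth)) {
    if (!all(as.integer(names(truth[[v]])) %in% task$horizons)) {
      stop("truth outside configured horizons for ", v)
    }
  }
  structure(list(patient_id = patient_id, t0 = t0, history = history,
                 statics = statics, baseline = baseline, truth = truth,
                 horizons = task$horizons, targets = task$targets,
                 unit_label = task$unit_label),
            class = "forecast_example")
}

#' @export
print.forecast_example <- function(x, ...) {
  cat(sprintf("<forecast_example> patient %s, landmark bin %g, %d history obs, %d target(s) with future truth\n",
              x$patient_id, x$t0, nrow(x$history), length(x$truth)))
  invisible(x)
}

# Number of observed future points per target (T_i in the error metrics).
example_T <- function(example) {
  vapply(example$truth, length, integer(1L))
}
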