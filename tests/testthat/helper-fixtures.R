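# Shared fixtures, all built in code.

mini_registry <- function() {
  variable_registry(
    variable_spec("hb", unit = "g/dL", role = "target",
                  reference_range = c(12, 16)),
    variable_spec("wbc", unit = "10^9/L", role = "target",
                  reference_range = c(4.5, 11)),
    variable_spec("therapy", kind = "categorical", role = "covariate"),
    variable_spec("sex", kind = "categorical", role = "static"))
}

mini_task <- function(horizons = 1:4) {
  task_config(bin_width = 7, horizons = horizons, targets = c("hb", "wbc"),
              landmark_policy = "therapy_start", unit_label = "week")
}

# Hand-built binned cohort with two patients and a therapy landmark at bin 0.
mini_cohort <- function() {
  obs <- rbind(
    data.frame(patient_id = "A", variable = "hb",
               time = c(-3, -1, 1, 2, 4), value = c("11.0", "11.5", "11.2", "10.8", "10.5")),
    data.frame(patient_id = "A", variable = "wbc",
               time = c(-2, 1, 3), value = c("6.0", "6.5", "7.0")),
    data.frame(patient_id = "A", variable = "therapy",
               time = 0, value = "chemo"),
    data.frame(patient_id = "B", variable = "hb",
               time = c(-2, 2, 3), value = c("13.0", "13.4", "13.8")),
    data.frame(patient_id = "B", variable = "therapy",
               time = 0, value = "immuno"))
  statics <- data.frame(
    patient_id = c("A", "A", "B", "B"),
    attribute = c("sex", "ecog", "sex", "ecog"),
    value = c("female", "1", "male", "0"))
  cohort(obs, statics, binned = TRUE)
}

# A random forecast example with distinct rendered values (for substring
# counting) and contiguous truth offsets.
random_example <- function(seed, n_targets = 2L, horizons = 1:4) {
  withr::with_seed(seed, {
    targets <- paste0("var_", letters[seq_len(n_targets)])
    task <- task_config(bin_width = 1, horizons = horizons, targets = targets,
                        landmark_policy = "baseline_only", unit_label = "week")
    hist_times <- sort(sample(-6:0, sample(2:5, 1)))
    vals <- round(seq(5, 40, by = 0.7) + stats::runif(1), 1)
    used <- 0L
    rows <- list()
    for (v in targets) {
      tt <- sort(sample(hist_times, sample(seq_along(hist_times), 1)))
      for (t in tt) {
        used <- used + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = "X", variable = v, time = t,
          value = formatC(vals[used], format = "f", digits = 1))
      }
    }
    hist <- do.call(rbind, rows)
    truth <- list()
    for (v in targets) {
      offs <- sort(sample(horizons, sample(seq_along(horizons), 1)))
      used_t <- length(unlist(truth)) + used
      truth[[v]] <- stats::setNames(
        round(stats::runif(length(offs), 5, 40), 1), as.character(offs))
    }
    baseline <- stats::setNames(rep(NA_real_, n_targets), targets)
    hnum <- suppressWarnings(as.numeric(hist$value))
    for (v in targets) {
      sel <- which(hist$variable == v)
      if (length(sel)) baseline[[v]] <- hnum[sel[which.max(hist$time[sel])]]
    }
    forecast_example(patient_id = "X", t0 = 0, history = hist,
                     statics = c(sex = "female"), baseline = baseline,
                     truth = truth, task = task)
  })
}

# Random small evaluation panels plus the parallel oracle structure.
random_panel <- function(seed, n_targets = 3L, max_units = 10L,
                         max_points = 8L) {
  withr::with_seed(seed, {
    targets <- paste0("v", seq_len(n_targets))
    n_units <- sample(2:max_units, 1)
    rows <- list()
    oracle <- stats::setNames(vector("list", n_targets), targets)
    for (u in seq_len(n_units)) {
      unit <- sprintf("U%02d", u)
      for (v in targets) {
        Ti <- sample(seq_len(max_points), 1)
        offs <- sort(sample(seq_len(max_points), Ti))
        truth <- round(stats::runif(Ti, 5, 15), 3)
        pred <- round(stats::runif(Ti, 5, 15), 3)
        v0 <- round(stats::runif(1, 5, 15), 3)
        rows[[length(rows) + 1L]] <- data.frame(
          unit = unit, patient_id = unit, variable = v, offset = offs,
          truth = truth, pred = pred, v0 = v0)
        oracle[[v]][[length(oracle[[v]]) + 1L]] <-
          list(truth = truth, pred = pred, v0 = v0)
      }
    }
    list(panel = do.call(rbind, rows), oracle = oracle, targets = targets)
  })
}

# Fit (once per session) the small echo-backend model used by several tests.
echo_fit_cache <- new.env(parent = emptyenv())
cached_echo_fit <- function() {
  if (is.null(echo_fit_cache$fit)) {
    sim <- simulate_cohort(cohort_config(n_patients = 40, seed = 31))
    task <- task_config(bin_width = 7, horizons = 1:13,
                        targets = c("hemoglobin", "leukocytes", "neutrophils"),
                        landmark_policy = "therapy_start", unit_label = "week")
    echo_fit_cache$fit <- twin_forecaster(
      sim$cohort, task, registry = nsclc_registry(),
      backend = backend_echo(), k = 3, seed = 17)
  }
  echo_fit_cache$fit
}
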