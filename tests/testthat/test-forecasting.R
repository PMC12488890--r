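test_that("ensemble sampling keeps full parse accounting", {
  ex <- random_example(11)
  enc <- encode_example(ex, observed_only = FALSE)

  echo <- fine_tune(backend_echo(), list(encode_example(ex)))
  ens <- sample_trajectories(echo, enc, k = 5)
  expect_equal(ens$k, 5L)
  expect_true(all(vapply(ens$decoded, `[[`, character(1), "status") == "ok"))

  garbage <- backend_canned("complete nonsense")
  ens2 <- sample_trajectories(garbage, enc, k = 4)
  expect_true(all(vapply(ens2$decoded, `[[`, character(1), "status") == "failed"))
  expect_equal(ens2$cell_counts$n_parsed, rep(0L, nrow(enc$schema)))

  # mixed backend: 2 valid answers, 1 garbage -> per-cell count 2
  good <- generate_text(echo, enc$input, k = 1, schema = enc$schema)
  mixed <- backend_canned(c(good, good, "garbage"))
  ens3 <- sample_trajectories(mixed, enc, k = 3)
  expect_equal(ens3$cell_counts$n_parsed, rep(2L, nrow(enc$schema)))
})

test_that("mean aggregation averages parsed cells and falls back flagged", {
  ex <- random_example(12)
  enc <- encode_example(ex, observed_only = FALSE)
  v <- enc$schema$variable[1]
  o <- as.character(enc$schema$offset[1])
  label <- enc$schema$label[1]

  mk <- function(val) sprintf('{"%s": {"%s": %s}}', v, label, val)
  be <- backend_canned(c(mk(10), mk(14)))
  ens <- sample_trajectories(be, enc, k = 2)
  agg <- aggregate_mean(ens)
  expect_equal(unname(agg[[v]][o]), 12)

  # idempotence on identical samples
  be2 <- backend_canned(mk(9.5))
  agg2 <- aggregate_mean(sample_trajectories(be2, enc, k = 3))
  expect_equal(unname(agg2[[v]][o]), 9.5)

  # unparsed cells fall back to the supplied trajectory, flagged
  fallback <- copy_forward_forecast(ex)
  agg3 <- aggregate_mean(sample_trajectories(backend_canned("nope"), enc,
                                             k = 3),
                         fallback = fallback)
  expect_equal(agg3[names(fallback)], fallback[names(fallback)],
               ignore_attr = TRUE)
  expect_gt(nrow(attr(agg3, "fallback_cells")), 0L)

  # random ensembles equal a brute-force per-cell mean
  echo <- fine_tune(backend_echo(), list(encode_example(ex)))
  ens4 <- sample_trajectories(echo, enc, k = 4)
  agg4 <- aggregate_mean(ens4)
  for (j in seq_len(nrow(enc$schema))) {
    vv <- enc$schema$variable[j]; oo <- as.character(enc$schema$offset[j])
    vals <- unlist(lapply(ens4$decoded, function(d) d$values[[vv]][oo]))
    expect_equal(unname(agg4[[vv]][oo]), mean(vals[!is.na(vals)]))
  }
})

test_that("the oracle trajectory minimizes per-example scaled MAE", {
  ex <- random_example(13)
  enc <- encode_example(ex, observed_only = FALSE)
  sigma <- stats::setNames(rep(2, length(ex$targets)), ex$targets)

  echo <- fine_tune(backend_echo(), list(encode_example(ex)))
  ens1 <- sample_trajectories(echo, enc, k = 1)
  o1 <- oracle_best_trajectory(ens1, ex$truth, sigma)
  expect_equal(o1$index, 1L)

  # construct two full-grid answers with known scaled MAE ordering
  full_json <- function(shift) {
    parts <- vapply(unique(enc$schema$variable), function(v) {
      sub <- enc$schema[enc$schema$variable == v, ]
      cells <- paste0('"', sub$label, '": ',
                      formatC(10 + shift, format = "f", digits = 1))
      paste0('"', v, '": {', paste(cells, collapse = ", "), "}")
    }, character(1))
    paste0("{", paste(parts, collapse = ", "), "}")
  }
  be <- backend_canned(c(full_json(5), full_json(0), full_json(9)))
  ens <- sample_trajectories(be, enc, k = 3)
  o <- oracle_best_trajectory(ens, ex$truth, sigma)
  scores <- vapply(ens$decoded, function(d) {
    twinforecast:::example_scaled_mae(d$values, ex$truth, sigma)
  }, numeric(1))
  expect_equal(o$index, which.min(scores))
  expect_equal(o$scaled_mae, min(scores))
  expect_true(all(o$scaled_mae <= scores))

  # no parsed samples is an error
  bad <- sample_trajectories(backend_canned("x"), enc, k = 2)
  expect_error(oracle_best_trajectory(bad, ex$truth, sigma), "no fully parsed")
})

test_that("copy-forward repeats the last value or the training median", {
  task <- mini_task()
  ex <- forecast_example(
    patient_id = "A", t0 = 0,
    history = data.frame(patient_id = "A", variable = "hb", time = c(-2, 0),
                         value = c("11.0", "12.0")),
    statics = c(sex = "female"), baseline = c(hb = 12.0, wbc = NA),
    truth = list(hb = c("1" = 12.0, "2" = 12.0)), task = task)
  stats_tr <- list(median = c(hb = 10.0, wbc = 9.8))
  cf <- copy_forward_forecast(ex, stats_tr)
  expect_equal(unname(cf$hb), rep(12.0, 4))
  expect_equal(unname(cf$wbc), rep(9.8, 4))
  expect_identical(attr(cf, "imputed"), "wbc")

  # constant history forecasts perfectly iff the future is constant
  panel <- forecast_panel(list(cf), list(ex))
  err <- forecast_errors(panel[panel$variable == "hb", ], c(hb = 1))
  expect_equal(err$MAE, 0)
})

test_that("the linear reference recovers exact linear structure", {
  task <- task_config(bin_width = 7, horizons = 1:2, targets = "hb",
                      landmark_policy = "baseline_only", unit_label = "week")
  mk_ex <- function(id, v0, gap, truth_fun) {
    hist <- data.frame(patient_id = id, variable = "hb", time = -gap,
                       value = as.character(v0))
    forecast_example(patient_id = id, t0 = 0, history = hist,
                     statics = character(0), baseline = c(hb = v0),
                     truth = list(hb = stats::setNames(truth_fun(v0), c("1", "2"))),
                     task = task)
  }
  withr::local_seed(5)
  train <- lapply(1:20, function(i) {
    mk_ex(paste0("T", i), round(runif(1, 8, 14), 1), sample(1:4, 1),
          function(v) c(2 * v, 2 * v))
  })
  test_ex <- mk_ex("X", 11.3, 2, function(v) c(2 * v, 2 * v))
  pred <- linear_reference_forecast(train, list(test_ex),
                                    statics_vars = character(0))
  expect_equal(unname(pred[[1]]$hb), c(22.6, 22.6), tolerance = 1e-6)

  # constant training target predicts the constant
  train_c <- lapply(1:5, function(i) {
    mk_ex(paste0("C", i), round(runif(1, 8, 14), 1), 1, function(v) c(7, 7))
  })
  pred_c <- linear_reference_forecast(train_c, list(test_ex),
                                      statics_vars = character(0))
  expect_equal(unname(pred_c[[1]]$hb), c(7, 7), tolerance = 1e-8)

  # under 2 training rows: copy-forward fallback, flagged
  pred_f <- linear_reference_forecast(train[1], list(test_ex),
                                      statics_vars = character(0))
  expect_equal(unname(pred_f[[1]]$hb), rep(11.3, 2))
  expect_gt(attr(pred_f, "fallback_cells"), 0L)
})
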