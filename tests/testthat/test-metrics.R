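make_panel <- function(units) {
  # units: list of list(truth=, pred=, v0=), one target "v"
  rows <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    data.frame(unit = paste0("U", i), patient_id = paste0("U", i),
               variable = "v", offset = seq_along(u$truth),
               truth = u$truth, pred = u$pred, v0 = u$v0)
  })
  do.call(rbind, rows)
}

test_that("the worked single-patient example reproduces the hand arithmetic", {
  panel <- make_panel(list(list(truth = c(10, 20), pred = c(12, 16), v0 = 10)))
  err <- forecast_errors(panel, sigma = c(v = 5))
  expect_equal(err$MAE, 3.0)
  expect_equal(err$scaled_MAE, 0.6)
  expect_equal(err$MASE, 0.6)
  expect_equal(err$SMAPE, 200 * (2 / 22 + 4 / 36) / 2)
  expect_equal(round(err$SMAPE, 3), 20.202)
})

test_that("errors are nested per patient, not pooled", {
  panel <- make_panel(list(list(truth = c(10), pred = c(14), v0 = 1),
                           list(truth = c(10, 10), pred = c(11, 13), v0 = 1)))
  err <- forecast_errors(panel, sigma = c(v = 1))
  expect_equal(err$MAE, 3.0) # mean(4, mean(1, 3)), not 8/3
})

test_that("closed-form anchors hold", {
  withr::local_seed(19)
  units <- lapply(1:5, function(i) {
    truth <- round(runif(4, 5, 15), 1)
    list(truth = truth, pred = truth, v0 = round(runif(1, 5, 15), 1))
  })
  perfect <- make_panel(units)
  err <- forecast_errors(perfect, sigma = c(v = 2))
  expect_equal(err$MAE, 0)
  expect_equal(err$scaled_MAE, 0)
  expect_equal(err$MASE, 0)
  expect_equal(err$SMAPE, 0)
  expect_equal(spearman_weighted(perfect)$spearman_rho, 1)

  # predicting the baseline value everywhere makes MASE exactly 1
  baseline_pred <- make_panel(lapply(units, function(u) {
    list(truth = u$truth, pred = rep(u$v0, length(u$truth)), v0 = u$v0)
  }))
  expect_equal(forecast_errors(baseline_pred, sigma = c(v = 2))$MASE, 1)

  # scaled MAE is exactly MAE / sigma
  rnd <- make_panel(lapply(1:7, function(i) {
    list(truth = runif(3), pred = runif(3), v0 = runif(1))
  }))
  e <- forecast_errors(rnd, sigma = c(v = 1.37))
  expect_identical(e$scaled_MAE, e$MAE / 1.37)

  # anti-monotone predictions with one point per patient give rho = -1
  anti <- make_panel(lapply(1:6, function(i) {
    list(truth = i, pred = -i, v0 = 0)
  }))
  expect_equal(spearman_weighted(anti)$spearman_rho, -1)
})

test_that("MASE excludes patients without a usable baseline", {
  panel <- make_panel(list(
    list(truth = c(10, 20), pred = c(12, 16), v0 = 10),
    list(truth = c(5, 5), pred = c(6, 6), v0 = NA_real_),    # no baseline
    list(truth = c(7, 7), pred = c(8, 8), v0 = 7)))          # zero denominator
  err <- forecast_errors(panel, sigma = c(v = 5))
  expect_equal(err$mase_excluded, 2L)
  expect_equal(err$MASE, 0.6) # only the first patient is eligible
  expect_equal(err$MAE, mean(c(3, 1, 1))) # MAE itself keeps everyone
})

test_that("reference labeling uses the closed-interval convention", {
  expect_identical(label_reference(13.0, c(14, 18)), "low")
  expect_identical(label_reference(c(14, 18), c(14, 18)),
                   c("normal", "normal"))
  withr::with_seed(3, v <- runif(200, 0, 30))
  brute <- vapply(v, oracle_label, character(1), vmin = 10, vmax = 20)
  expect_identical(label_reference(v, c(10, 20)), brute)
})

test_that("reference-range AUCs match two-point and weighted arithmetic", {
  # truth labels (low, normal) with predictions on the right side
  a <- auc_reference(pred = c(4.0, 6.0), truth = c(4.0, 6.0),
                     range = c(4.5, 100))
  expect_equal(a$AUC_low, 1.0)
  b <- auc_reference(pred = c(6.0, 4.0), truth = c(4.0, 6.0),
                     range = c(4.5, 100))
  expect_equal(b$AUC_low, 0.0)

  # all prediction scores equal: every defined AUC is 0.5
  c3 <- auc_reference(pred = rep(5, 4), truth = c(1, 5, 5, 30),
                      range = c(4, 10))
  expect_equal(c3$AUC_low, 0.5)
  expect_equal(c3$AUC_high, 0.5)
  expect_equal(c3$AUC_normal, 0.5)

  # weighted aggregation: AUCs (1, .5, 1) with counts (1, 1, 1)
  d <- auc_reference(pred = c(1, 7, 7.2, 30), truth = c(1, 7, 7.2, 30),
                     range = c(4, 10))
  w <- (d$AUC_low * d$n_low + d$AUC_normal * d$n_normal +
          d$AUC_high * d$n_high) / (d$n_low + d$n_normal + d$n_high)
  expect_equal(d$AUC_weighted, w)

  # randomized check against the pair-counting oracle
  for (s in 1:20) {
    withr::with_seed(s, {
      truth <- runif(30, 0, 30)
      pred <- truth + rnorm(30, sd = 5)
    })
    got <- auc_reference(pred, truth, c(8, 20))
    want <- oracle_auc_reference(pred, truth, 8, 20)
    expect_equal(got$AUC_low, want$low)
    expect_equal(got$AUC_high, want$high)
    expect_equal(got$AUC_normal, want$normal)
    expect_equal(got$AUC_weighted, want$weighted)
  }
})

test_that("sex-conditional ranges resolve per patient", {
  reg <- nsclc_registry()
  expect_equal(reference_range_for(reg, "hemoglobin", c(sex = "male")),
               c(14, 18))
  expect_equal(reference_range_for(reg, "hemoglobin", c(sex = "female")),
               c(12, 16))
  expect_null(reference_range_for(reg, "hemoglobin", c(sex = "unknown")))
  # 13.0 g/dL is low for a male patient, normal for a female patient
  expect_identical(label_reference(13, reference_range_for(reg, "hemoglobin",
                                                           c(sex = "male"))),
                   "low")
  expect_identical(label_reference(13, reference_range_for(reg, "hemoglobin",
                                                           c(sex = "female"))),
                   "normal")
})

test_that("trend labels follow the strict lookback rule", {
  # constant trajectory: never increasing or decreasing
  lab <- trend_labels(rep(5, 4), 0:3, s = 2)
  expect_true(all(lab %in% c("excluded", "neither")))

  # the worked case: (5,4,3,3) at times 0..3, s = 2
  lab2 <- trend_labels(c(5, 4, 3, 3), 0:3, s = 2)
  expect_identical(lab2, c("excluded", "excluded", "decreasing", "neither"))

  # a missing grid point inside the window excludes the point
  lab3 <- trend_labels(c(5, 4, 3), c(0, 1, 3), s = 2)
  expect_identical(lab3[3], "excluded")
})

test_that("trend AUCs separate perfectly reproduced trends and tie at 0.5", {
  trajs <- list(c("0" = 5, "1" = 4, "2" = 3, "3" = 2),
                c("0" = 2, "1" = 3, "2" = 4, "3" = 5),
                c("0" = 4, "1" = 6, "2" = 3, "3" = 4))
  perfect <- auc_trend(trajs, trajs, s = 2)
  expect_equal(perfect$AUC_trend_down, 1)
  expect_equal(perfect$AUC_trend_up, 1)

  flat <- lapply(trajs, function(t) stats::setNames(rep(4, 4), names(t)))
  tied <- auc_trend(trajs, flat, s = 2)
  expect_equal(tied$AUC_trend_down, 0.5)
  expect_equal(tied$AUC_trend_up, 0.5)
})

test_that("KS distance matches ECDF arithmetic and stats::ks.test", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2), c(10, 20)), 1)
  expect_equal(ks_statistic(c(1, 3), c(1, 2)), 0.5)
  withr::with_seed(8, {
    x <- rnorm(50)
    y <- rnorm(60, 0.3)
  })
  expect_equal(ks_statistic(x, y),
               unname(stats::ks.test(x, y)$statistic))
  expect_equal(ks_statistic(x, y), oracle_ks(x, y))
})

test_that("correlation preservation is 1 for perfect and NA for degenerate", {
  rp <- random_panel(42, n_targets = 3)
  panel <- rp$panel
  panel$pred <- panel$truth
  expect_equal(correlation_preservation(panel)$r_squared, 1)

  panel2 <- rp$panel
  panel2$pred <- 7
  out <- correlation_preservation(panel2)
  expect_true(is.na(out$r_squared))
})
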