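test_that("binning keeps the last observed value per week", {
  one <- cohort(data.frame(patient_id = "A", variable = "hb", time = 3,
                           value = "5"))
  b <- bin_last_observed(one, 7)
  expect_equal(b$observations$time, 0)
  expect_equal(b$observations$value, "5")

  two <- cohort(data.frame(patient_id = "A", variable = "hb",
                           time = c(1, 3), value = c("5", "7")))
  b2 <- bin_last_observed(two, 7)
  expect_equal(nrow(b2$observations), 1L)
  expect_equal(b2$observations$value, "7")
})

test_that("binning a 500-observation record matches a brute-force group-by", {
  withr::with_seed(101, {
    obs <- data.frame(patient_id = sample(c("A", "B"), 500, TRUE),
                      variable = sample(c("hb", "wbc", "ldh"), 500, TRUE),
                      time = round(stats::runif(500, -50, 80), 2),
                      value = as.character(round(stats::runif(500, 1, 20), 1)))
  })
  binned <- bin_last_observed(cohort(obs), 7)$observations

  # brute force: for each (patient, variable, bin), value at the max raw time
  # (last input row on exact ties)
  brute <- list()
  bins <- floor(obs$time / 7)
  for (p in unique(obs$patient_id)) for (v in unique(obs$variable)) {
    sel <- which(obs$patient_id == p & obs$variable == v)
    for (b in sort(unique(bins[sel]))) {
      rows <- sel[bins[sel] == b]
      winner <- rows[obs$time[rows] == max(obs$time[rows])]
      winner <- winner[length(winner)]
      brute[[length(brute) + 1L]] <- data.frame(
        patient_id = p, variable = v, time = b, value = obs$value[winner])
    }
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$patient_id, brute$variable, brute$time), ]
  rownames(brute) <- NULL
  expect_equal(binned, brute)

  # idempotence
  rebinned <- bin_last_observed(cohort(binned, binned = TRUE), 7)
  expect_identical(rebinned$observations, binned)
})

test_that("two-step outlier filter follows the filter-then-clip procedure", {
  # constant values: untouched, degenerate sd flagged
  const <- cohort(data.frame(patient_id = paste0("P", 1:20), variable = "hb",
                             time = 0, value = "1"), binned = TRUE)
  res <- filter_outliers(const, "hb")
  expect_true(res$bounds$degenerate)
  expect_equal(res$cohort$observations$value, rep("1", 20))

  # 20 ones plus a 100: the 100 is outside mean +/- 3 sd and removed in step
  # 1; survivors (constant) are unchanged and step-2 sd is 0
  vals <- c(rep(1, 20), 100)
  spiked <- cohort(data.frame(patient_id = paste0("P", seq_along(vals)),
                              variable = "hb", time = 0,
                              value = as.character(vals)), binned = TRUE)
  m1 <- mean(vals); s1 <- sd(vals)
  expect_gt(abs(100 - m1), 3 * s1) # the premise of the fixture
  expect_lt(abs(1 - m1), 3 * s1)
  res2 <- filter_outliers(spiked, "hb")
  expect_equal(res2$bounds$n_removed_step1, 1L)
  expect_equal(nrow(res2$cohort$observations), 20L)
  expect_equal(res2$cohort$observations$value, rep("1", 20))
  expect_true(res2$bounds$degenerate)
  # step-2 statistics computed on survivors only, not the full data
  expect_equal(res2$bounds$mean2, 1)
  expect_equal(res2$bounds$sd2, 0)

  # large standard-normal sample: ~0.27% removed, remainder inside recomputed
  # bounds after clipping
  withr::with_seed(7, x <- stats::rnorm(10000))
  norm <- cohort(data.frame(patient_id = paste0("P", seq_along(x)),
                            variable = "hb", time = 0,
                            value = as.character(x)), binned = TRUE)
  res3 <- filter_outliers(norm, "hb")
  frac_removed <- res3$bounds$n_removed_step1 / 10000
  expect_gt(frac_removed, 0.0005)
  expect_lt(frac_removed, 0.007)
  kept <- as.numeric(res3$cohort$observations$value)
  expect_true(all(kept >= res3$bounds$lo2 - 1e-12))
  expect_true(all(kept <= res3$bounds$hi2 + 1e-12))
})

test_that("patient splits are exact, deterministic, and stratified", {
  ids <- paste0("P", 1:10)
  sp <- split_patients(ids, c(train = .8, validation = .1, test = .1),
                       seed = 4)
  expect_equal(lengths(sp), c(train = 8L, validation = 1L, test = 1L))
  expect_equal(sort(unname(unlist(sp))), sort(ids))
  expect_identical(sp, split_patients(ids, c(train = .8, validation = .1,
                                             test = .1), seed = 4))

  # disjointness and coverage over many random cohorts
  for (s in 1:100) {
    n <- sample(3:40, 1)
    ids <- paste0("Q", seq_len(n))
    sp <- split_patients(ids, c(train = .8, validation = .1, test = .1),
                         seed = s)
    all_ids <- unname(unlist(sp))
    expect_equal(sort(all_ids), sort(ids))
    expect_equal(anyDuplicated(all_ids), 0L)
  }

  # binary stratum 30/70 at n = 1000: each split reproduces the mix to 2%
  n <- 1000L
  strat <- rep(c("early", "late"), c(300, 700))
  obs <- data.frame(patient_id = sprintf("R%04d", 1:n), variable = "hb",
                    time = 0, value = "1")
  statics <- data.frame(patient_id = obs$patient_id, attribute = "stage",
                        value = strat)
  co <- cohort(obs, statics, binned = TRUE)
  sp <- split_patients(co, c(train = .8, validation = .1, test = .1),
                       strata = "stage", seed = 9)
  for (part in sp) {
    mix <- mean(statics$value[match(part, statics$patient_id)] == "early")
    expect_lt(abs(mix - 0.3), 0.02)
  }

  # a stratum smaller than the number of splits falls back with a warning
  small_statics <- statics
  small_statics$value[1] <- "rare"
  co2 <- cohort(obs, small_statics, binned = TRUE)
  expect_warning(split_patients(co2, c(train = .8, validation = .1,
                                       test = .1),
                                strata = "stage", seed = 2),
                 "smaller than")
})

test_that("landmark construction never leaks future data", {
  task <- mini_task()
  # no therapy events: vacuous under therapy_start
  no_event <- cohort(data.frame(patient_id = "A", variable = "hb",
                                time = c(-1, 1), value = c("10", "11")),
                     binned = TRUE)
  expect_length(make_examples(no_event, task), 0L)

  # ICU-style fixed history: one example, history first 24 h, horizons 1..24
  icu_task <- task_config(bin_width = 1, horizons = 1:24, targets = "spo2",
                          landmark_policy = "fixed_history",
                          history_bins = 24L, unit_label = "hour")
  obs <- data.frame(patient_id = "A", variable = "spo2", time = 0:48,
                    value = as.character(round(stats::runif(49, 90, 99), 1)))
  ex <- make_examples(bin_last_observed(cohort(obs), 1), icu_task)
  expect_length(ex, 1L)
  expect_true(all(ex[[1]]$history$time >= -24 & ex[[1]]$history$time <= 0))
  expect_setequal(as.integer(names(ex[[1]]$truth$spo2)), 1:24)

  # two therapy lines: two examples, exhaustive leakage scan
  obs2 <- rbind(
    data.frame(patient_id = "B", variable = "hb", time = -5:10,
               value = as.character(round(stats::runif(16, 9, 14), 1))),
    data.frame(patient_id = "B", variable = "therapy", time = c(0, 6),
               value = c("lineA", "lineB")))
  ex2 <- make_examples(cohort(obs2, binned = TRUE), task)
  expect_length(ex2, 2L)
  for (e in ex2) {
    expect_true(all(e$history$time <= 0))
    for (v in names(e$truth)) {
      expect_true(all(as.integer(names(e$truth[[v]])) %in% task$horizons))
    }
  }

  # property: over random records no example history crosses its landmark
  for (s in 1:25) {
    withr::with_seed(s, {
      obs <- rbind(
        data.frame(patient_id = "Z", variable = sample(c("hb", "wbc"), 30, TRUE),
                   time = sample(-10:10, 30, TRUE),
                   value = as.character(round(stats::runif(30, 5, 15), 1))),
        data.frame(patient_id = "Z", variable = "therapy",
                   time = sample(-5:5, 2), value = c("a", "b")))
    })
    exs <- make_examples(bin_last_observed(cohort(obs), 7), mini_task())
    for (e in exs) expect_true(all(e$history$time <= 0))
  }
})

test_that("dropped examples without future truth are accounted for", {
  # therapy at bin 0 but no target values after it
  obs <- rbind(
    data.frame(patient_id = "A", variable = "hb", time = -2, value = "10"),
    data.frame(patient_id = "A", variable = "therapy", time = 0, value = "x"))
  ex <- make_examples(cohort(obs, binned = TRUE), mini_task())
  expect_length(ex, 0L)
  expect_equal(nrow(attr(ex, "dropped")), 1L)
})

test_that("cohort CSV round trip preserves the data", {
  co <- mini_cohort()
  obs_path <- withr::local_tempfile(fileext = ".csv")
  st_path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, obs_path, st_path)
  back <- read_cohort(obs_path, st_path, binned = TRUE)
  expect_equal(back$observations, co$observations)
  expect_equal(back$statics, co$statics)
})
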