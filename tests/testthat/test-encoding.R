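test_that("input encoding is deterministic and renders every observation once", {
  ex <- random_example(1)
  t1 <- encode_input(ex)
  t2 <- encode_input(ex)
  expect_identical(t1, t2)

  # every observed value's rendered "variable=value" string occurs exactly
  # once per observation carrying it
  rendered <- paste0(ex$history$variable, "=", ex$history$value)
  for (r in unique(rendered)) {
    hits <- gregexpr(r, t1, fixed = TRUE)[[1]]
    expect_equal(sum(hits > 0), sum(rendered == r))
  }

  # empty history: only sections 2-4, no history header
  ex0 <- ex
  ex0$history <- ex$history[0, ]
  t0 <- encode_input(ex0)
  expect_false(grepl("Patient history:", t0, fixed = TRUE))
  expect_true(grepl("Patient information:", t0, fixed = TRUE))
  expect_true(grepl("Forecast dates:", t0, fixed = TRUE))
})

test_that("target encoding produces exactly the observed cells", {
  task <- task_config(bin_width = 7, horizons = 1:4, targets = "hemoglobin",
                      landmark_policy = "baseline_only", unit_label = "week")
  ex <- forecast_example(
    patient_id = "A", t0 = 0,
    history = data.frame(patient_id = "A", variable = "hemoglobin",
                         time = 0, value = "12.0"),
    statics = c(sex = "female"), baseline = c(hemoglobin = 12.0),
    truth = list(hemoglobin = c("1" = 11.2)), task = task)
  expect_identical(encode_target(ex), '{"hemoglobin": {"week 1": 11.2}}')

  # interleaved missing cells: the JSON has exactly the observed cells
  ex2 <- random_example(5)
  json <- encode_target(ex2)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_setequal(names(parsed), names(ex2$truth))
  for (v in names(ex2$truth)) {
    expect_equal(length(parsed[[v]]), length(ex2$truth[[v]]))
  }
})

test_that("encode -> decode round trips exactly on 1000 random examples", {
  for (s in 1:1000) {
    ex <- random_example(s)
    enc <- encode_example(ex, observed_only = TRUE)
    dec <- decode_forecast(enc$target, enc$schema)
    expect_identical(dec$status, "ok")
    expect_equal(dec$n_extracted, dec$n_expected)
    for (v in names(ex$truth)) {
      expect_identical(dec$values[[v]][names(ex$truth[[v]])],
                       ex$truth[[v]])
    }
  }
})

test_that("decoding tolerates prose and reports failures as data", {
  ex <- random_example(2)
  enc <- encode_example(ex, observed_only = TRUE)
  wrapped <- paste0("Sure! Here is the forecast you asked for:\n",
                    enc$target, "\nLet me know if you need anything else.")
  dec <- decode_forecast(wrapped, enc$schema)
  expect_identical(dec$status, "ok")

  dec2 <- decode_forecast("no json here", enc$schema)
  expect_identical(dec2$status, "failed")
  expect_equal(dec2$n_extracted, 0L)

  # a broken brace-blob followed by a valid object still decodes
  dec3 <- decode_forecast(paste0("{oops", "} ", enc$target), enc$schema)
  expect_identical(dec3$status, "ok")

  # partial: schema expects a cell the answer does not contain
  dec4 <- decode_forecast(enc$target, rbind(enc$schema,
    data.frame(variable = "ghost", offset = 9L, label = "week 9")))
  expect_identical(dec4$status, "partial")
  expect_true(dec4$n_extracted < dec4$n_expected)
})

test_that("misspelling operations obey the edit-distance contract", {
  ex <- random_example(3)
  text <- encode_input(ex)
  expect_identical(inject_misspellings(text, 0, seed = 1), text,
                   ignore_attr = TRUE)

  # one operation: length changes by at most 1, Levenshtein distance <= 2
  for (s in 1:1000) {
    out <- inject_misspellings(text, 1, seed = s)
    expect_lte(abs(nchar(out) - nchar(text)), 1)
    expect_lte(utils::adist(out, text)[1, 1], 2)
  }

  # n operations are each logged, and distance grows by at most 2n
  long <- paste(rep(text, ceiling(10000 / nchar(text))), collapse = "")
  out25 <- inject_misspellings(long, 25, seed = 9)
  expect_equal(nrow(attr(out25, "ops")), 25L)
  expect_lte(utils::adist(out25, long)[1, 1], 50)

  # seeded determinism
  expect_identical(inject_misspellings(text, 10, seed = 4),
                   inject_misspellings(text, 10, seed = 4))

  # degenerate text: infeasible ops re-drawn as insertions, all logged
  out_empty <- inject_misspellings("", 3, seed = 2)
  expect_equal(nrow(attr(out_empty, "ops")), 3L)
  expect_gte(nchar(out_empty), 1L)
})

test_that("masking thins history Bernoulli-wise and never touches truth", {
  ex <- random_example(4)
  expect_identical(mask_observations(ex, 0), ex)
  gone <- mask_observations(ex, 1, seed = 1)
  expect_equal(nrow(gone$history), 0L)
  expect_identical(gone$truth, ex$truth)
  expect_identical(gone$baseline, ex$baseline)

  big <- ex
  big$history <- do.call(rbind, replicate(ceiling(10000 / nrow(ex$history)),
                                          ex$history, simplify = FALSE))
  n <- nrow(big$history)
  kept <- nrow(mask_observations(big, 0.5, seed = 8)$history)
  se <- sqrt(0.25 * n)
  expect_lt(abs((n - kept) - n / 2), 3 * se)
})

test_that("zero-shot prompts decode through the standard channel", {
  reg <- mini_registry()
  ex <- random_example(6)
  zp <- build_zero_shot_prompt(ex, reg, "wbc", offsets = 1:3)
  expect_true(grepl("wbc", zp$text, fixed = TRUE))
  expect_equal(nrow(zp$schema), 3L)
  answer <- '{"wbc": {"week 1": 6.1, "week 2": 6.4, "week 3": 7.0}}'
  dec <- decode_forecast(answer, zp$schema)
  expect_identical(dec$status, "ok")
  expect_equal(unname(dec$values$wbc), c(6.1, 6.4, 7.0))
  expect_error(build_zero_shot_prompt(ex, reg, "nonexistent", 1:3),
               "unknown variable")
})

test_that("explanation parsing extracts ranked registry mentions", {
  reg <- nsclc_registry()
  txt <- paste("The main driver was the therapy, followed by the patient's",
               "ecog status; leukocytes trends also contributed.")
  out <- parse_explanation(txt, reg)
  expect_identical(as.character(out), c("therapy", "ecog", "leukocytes"))
  expect_identical(attr(out, "status"), "ok")

  none <- parse_explanation("it just felt right", reg)
  expect_length(none, 0L)
  expect_identical(attr(none, "status"), "failed")
})
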