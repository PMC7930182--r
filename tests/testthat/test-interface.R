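test_that("cohort CSVs round-trip losslessly", {
  coh <- simulate_cohort(cohort_spec(n_patients = 36, seed = 23))
  mp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, mp, dp)
  back <- read_cohort(mp, dp)
  expect_equal(back$measurements, coh$measurements)
  expect_equal(back$metadata, coh$metadata)
  # 36 patients x 5 nominal visits minus missing week-3 samples
  expect_equal(nrow(back$measurements),
               36 * 5 - sum(!tapply(coh$measurements$week, coh$measurements$patient_id,
                                    function(w) 3 %in% w)))
})

test_that("cohort validation errors name the offending patients and rows", {
  coh <- simulate_cohort(cohort_spec(n_patients = 6, seed = 24))
  mp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")

  broken <- coh
  broken$measurements <- broken$measurements[
    !(broken$measurements$patient_id == "P003" & broken$measurements$week == 0), ]
  write_cohort(broken, mp, dp)
  expect_error(read_cohort(mp, dp), "P003")

  dup <- coh
  dup$measurements <- rbind(dup$measurements, dup$measurements[1, ])
  write_cohort(dup, mp, dp)
  expect_error(read_cohort(mp, dp), "duplicate")

  oob <- coh
  oob$measurements$cx3cr1_pct[4] <- 140
  write_cohort(oob, mp, dp)
  expect_error(read_cohort(mp, dp), "\\[0, 100\\]")

  badresp <- coh
  badresp$metadata$response[2] <- "XX"
  write_cohort(badresp, mp, dp)
  expect_error(read_cohort(mp, dp), "response")
})

test_that("repertoire TSVs round-trip and recompute missing frequencies", {
  r <- simulate_repertoire(repertoire_spec(n_clones = 40, total_templates = 999,
                                           seed = 25))
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire(r, tp)
  back <- read_repertoire(tp)
  expect_equal(back, r)

  # frequency column omitted: recomputed from counts
  raw <- readr::read_tsv(tp, show_col_types = FALSE)
  raw$frequencyCount <- NULL
  readr::write_tsv(raw, tp)
  back2 <- read_repertoire(tp)
  expect_equal(back2$frequency, r$count / sum(r$count))

  # inconsistent frequency column rejected
  raw$frequencyCount <- rev(r$frequency)
  readr::write_tsv(raw, tp)
  expect_error(read_repertoire(tp), "inconsistent")

  expect_error(read_repertoire("no/such/file.tsv"), "not found")
})

test_that("the full pipeline reproduces the published fixture metrics", {
  coh <- reference_cohort()
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.csv"); dp <- file.path(dir, "meta.csv")
  write_cohort(coh, mp, dp)
  cfg <- run_config(mp, dp, out_dir = file.path(dir, "out"))
  bundle <- run_pipeline(cfg)
  r12 <- bundle$reports$week_12$rates
  expect_equal(setNames(round(100 * r12$estimate, 1), r12$metric),
               c(sensitivity = 92.3, specificity = 87.0, ppv = 80.0,
                 npv = 95.2, accuracy = 88.9))
  expect_equal(bundle$reports$week_3$n, 27)
  expect_true(file.exists(file.path(dir, "out", "report.json")))
  expect_true(file.exists(file.path(dir, "out", "scores.csv")))

  # re-running yields byte-identical JSON
  dir2 <- file.path(dir, "out2")
  run_pipeline(run_config(mp, dp, out_dir = dir2))
  expect_identical(readLines(file.path(dir, "out", "report.json")),
                   readLines(file.path(dir2, "report.json")))
})

test_that("pipeline configuration is validated", {
  expect_error(run_config("m.csv", "d.csv", level = 1.2), "level")
  expect_error(run_config("m.csv", "d.csv", landmarks = c(-3, 6)), "landmarks")
  expect_error(run_config("m.csv", "d.csv", survival_landmark = 7), "survival_landmark")
  coh <- reference_cohort()
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.csv"); dp <- file.path(dir, "meta.csv")
  write_cohort(coh, mp, dp)
  cfg <- run_config(mp, dp, landmarks = c(3, 5), survival_landmark = 3)
  expect_error(run_pipeline(cfg), "landmark week")
})
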