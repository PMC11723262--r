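test_that("the end-to-end study driver runs, writes artifacts, and is seeded", {
  cfg <- default_run_config()
  cfg$generator$n_train <- 60
  cfg$generator$n_val <- 30
  cfg$generator$n_test <- 30
  cfg$generator$T <- 256L
  cfg$model$preset <- "hw"
  cfg$training$epochs <- 6L
  cfg$training$seeds <- 1L
  cfg$output_dir <- withr::local_tempdir()

  res <- run_benchmark_study(cfg, verbose = FALSE)
  expect_s3_class(res$reports[[1]], "eval_report")
  for (f in c("report.json", "per_freq_snr.csv", "confusion.csv",
              "accuracy_metrics.csv")) {
    expect_true(file.exists(file.path(cfg$output_dir, f)))
  }
  js <- jsonlite::read_json(file.path(cfg$output_dir, "report.json"))
  expect_true(all(c("summary", "per_freq_snr", "class_response") %in% names(js)))

  # determinism of the pipeline: same config, same summary
  cfg$output_dir <- withr::local_tempdir()
  res2 <- run_benchmark_study(cfg, verbose = FALSE)
  expect_equal(res$summary$snr_improvement_db, res2$summary$snr_improvement_db)
  expect_equal(res$summary$mse, res2$summary$mse)
})

test_that("stage failures are reported with the stage name", {
  cfg <- default_run_config()
  cfg$generator$n_train <- 6
  cfg$generator$n_val <- 3
  cfg$generator$n_test <- 3
  cfg$generator$T <- 64L
  cfg$model$preset <- "colossal"   # no such preset
  expect_error(run_benchmark_study(cfg, verbose = FALSE), "stage 'train'")
})
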