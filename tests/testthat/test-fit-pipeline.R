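sim_fit <- function(seed = 42) {
  cindex_fit(sample_cohort(default_cohort_config(seed = seed)))
}

test_that("the fitted object carries every table the analysis produces", {
  fit <- sim_fit()
  expect_s3_class(fit, "cindex_fit")
  # 3 biomarkers x 3 groups plus the index in each group
  expect_equal(nrow(fit$summaries), 12)
  expect_equal(sum(fit$summaries$marker != "cindex"), 9)
  expect_length(fit$tests, 4)
  expect_equal(nrow(fit$performance), 4)
  expect_identical(fit$performance$marker, c("pct", "crp", "il6", "cindex"))
  expect_equal(mean(fit$scores$cindex), 3, tolerance = 1e-12)
  expect_identical(attr(fit$ref, "source"), "cohort")
})

test_that("fitting is deterministic in its input", {
  co <- sample_cohort(default_cohort_config(seed = 7))
  r1 <- as_report(cindex_fit(co))
  r2 <- as_report(cindex_fit(co))
  expect_identical(r1, r2)
})

test_that("a single-class cohort cannot be fitted", {
  df <- make_cohort_df(n = 6)
  df$infection <- 0
  expect_error(cindex_fit(as_cohort(df)), "both classes")
})

test_that("coef, fitted and predict expose the model surface", {
  fit <- sim_fit()
  co <- fit$cohort
  expect_equal(unname(coef(fit)),
               c(mean(co$pct), mean(co$crp), mean(co$il6)))
  expect_equal(unname(fitted(fit)), fit$scores$cindex)
  expect_equal(predict(fit), fit$scores$cindex)
  expect_equal(predict(fit, co), fit$scores$cindex)
  cut <- fit$performance$cutoff[fit$performance$marker == "cindex"]
  cls <- predict(fit, type = "class")
  expect_identical(cls, as.numeric(fit$scores$cindex >= cut))
  # an episode at the fitted means scores 3
  at_mean <- data.frame(pct = coef(fit)[1], crp = coef(fit)[2],
                        il6 = coef(fit)[3])
  expect_equal(predict(fit, at_mean), 3, tolerance = 1e-12)
})

test_that("an external reference changes the scores, not the ROC ranking", {
  co <- sample_cohort(default_cohort_config(seed = 3))
  ref <- external_reference_means(2, 12, 150)
  fit <- cindex_fit(co, reference = ref)
  expect_identical(attr(fit$ref, "source"), "external")
  # the index is a positive linear functional either way, but with different
  # weights, so scores differ while staying finite and non-negative
  expect_true(all(fit$scores$cindex >= 0))
  base <- cindex_fit(co)
  expect_false(isTRUE(all.equal(fit$scores$cindex, base$scores$cindex)))
})

test_that("summary and print run and expose the test table", {
  fit <- sim_fit()
  s <- summary(fit)
  expect_identical(s$test_table$marker, c("pct", "crp", "il6", "cindex"))
  expect_true(all(s$test_table$p_value > 0 & s$test_table$p_value <= 1))
  expect_output(print(fit), "Composite-index")
  expect_output(print(s), "Wilcoxon")
})

test_that("simulate() draws cohorts shaped like the fitted one", {
  fit <- sim_fit()
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2)
  for (s in sims) {
    expect_equal(nrow(s), nrow(fit$cohort))
    expect_equal(sum(s$infection == 1), sum(fit$cohort$infection == 1))
  }
  expect_false(identical(sims[[1]]$pct, sims[[2]]$pct))
  expect_identical(simulate(fit, nsim = 1, seed = 99)[[1]], sims[[1]])
})

test_that("plot method draws without error", {
  fit <- sim_fit()
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot(fit, main = "ROC"))
  grDevices::dev.off()
  expect_true(file.size(path) > 0)
})

test_that("reports round-trip through JSON and cover every table", {
  fit <- sim_fit()
  dir <- withr::local_tempdir()
  write_report(fit, dir)
  files <- c("report.json", "summary.csv", "rank_tests.csv",
             "performance.csv", "cindex.csv", "roc_points.csv",
             "density_long.csv")
  expect_true(all(file.exists(file.path(dir, files))))
  rep <- jsonlite::read_json(file.path(dir, "report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$cohort$n, 51)
  expect_equal(rep$cohort$n_infection, 11)
  expect_equal(rep$performance$auc, fit$performance$auc, tolerance = 1e-12)
  perf_csv <- utils::read.csv(file.path(dir, "performance.csv"))
  expect_identical(perf_csv$marker, c("pct", "crp", "il6", "cindex"))
})

test_that("the pipeline entry point runs simulate then analyze end to end", {
  dir <- withr::local_tempdir()
  cohort_csv <- file.path(dir, "cohort.csv")
  report_dir <- file.path(dir, "report")
  expect_message(
    code1 <- pipeline_main(c("simulate", "--seed", "42", "--out", cohort_csv)),
    "wrote 51 episodes")
  expect_identical(code1, 0L)
  expect_true(file.exists(cohort_csv))
  expect_true(file.exists(file.path(dir, "cohort_fit.json")))

  expect_message(
    code2 <- pipeline_main(c("analyze", "--in", cohort_csv,
                             "--out", report_dir)),
    "report written")
  expect_identical(code2, 0L)
  expect_true(file.exists(file.path(report_dir, "report.json")))

  # same seed, second run: byte-identical cohort CSV
  csv2 <- file.path(dir, "cohort2.csv")
  suppressMessages(pipeline_main(c("simulate", "--seed", "42", "--out", csv2)))
  expect_identical(readLines(csv2), readLines(cohort_csv))
})

test_that("the pipeline fails loudly on bad input", {
  missing <- file.path(tempdir(), "no-such-cohort.csv")
  expect_message(code <- pipeline_main(c("analyze", "--in", missing,
                                         "--out", tempdir())),
                 "no-such-cohort")
  expect_gt(code, 0L)
  expect_message(usage <- pipeline_main(c("frobnicate")), "usage")
  expect_identical(usage, 2L)
  expect_message(bad <- pipeline_main(c("simulate", "--bogus", "1")), "usage")
  expect_identical(bad, 2L)
})

test_that("external reference means flow through the analyze subcommand", {
  dir <- withr::local_tempdir()
  cohort_csv <- file.path(dir, "cohort.csv")
  suppressMessages(pipeline_main(c("simulate", "--seed", "5",
                                   "--out", cohort_csv)))
  means_json <- file.path(dir, "means.json")
  jsonlite::write_json(list(pct = 2, crp = 12, il6 = 150), means_json,
                       auto_unbox = TRUE)
  out <- file.path(dir, "rep")
  suppressMessages(code <- pipeline_main(c("analyze", "--in", cohort_csv,
                                           "--reference-means", means_json,
                                           "--out", out)))
  expect_identical(code, 0L)
  rep <- jsonlite::read_json(file.path(out, "report.json"),
                             simplifyVector = TRUE)
  expect_identical(rep$reference_means$source, "external")
  expect_equal(rep$reference_means$pct, 2)
})
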