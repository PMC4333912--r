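# three readers whose pairwise overall PA values are 100, 50, 50
three_reader_ds <- function() {
  make_dataset(list(
    R1 = list(optical = c(10, 30, 60, 90)),
    R2 = list(optical = c(10, 30, 60, 90)),
    R3 = list(optical = c(10, 30, 20, 20))))
}

test_that("interobserver agreement is the unweighted mean over reader pairs", {
  est <- interobserver_agreement(three_reader_ds(), "HER2", "whole_slide",
                                 "optical", metric = "percent_overall")
  expect_equal(est$per_unit,
               c("R1|R2" = 100, "R1|R3" = 50, "R2|R3" = 50))
  expect_equal(est$point, 200 / 3)
  expect_equal(est$n_units, 3)
  expect_equal(est$n_units_defined, 3)
})

test_that("identical readers give perfect interobserver agreement", {
  v <- c(5, 30, 55, 80, 95)
  ds <- make_dataset(list(R1 = list(optical = v), R2 = list(optical = v),
                          R3 = list(optical = v)))
  expect_equal(interobserver_agreement(ds, "HER2", "whole_slide", "optical",
                                       metric = "tau_b")$point, 1)
  expect_equal(interobserver_agreement(ds, "HER2", "whole_slide", "optical",
                                       metric = "percent_overall")$point,
               100)
})

test_that("with two readers the average equals the single pair value", {
  ds <- make_dataset(list(R1 = list(optical = c(1, 2, 3, 3)),
                          R2 = list(optical = c(1, 3, 2, 3))))
  est <- interobserver_agreement(ds, "HER2", "whole_slide", "optical",
                                 metric = "tau_b")
  expect_equal(est$point, 0.4)
  expect_equal(unname(est$per_unit), 0.4)
})

test_that("point estimates are invariant to reader relabeling", {
  study <- generate_study(synthetic_study_config(
    "HER2", n_cases = c(tma_core = 20), seed = 31))
  rec <- study$dataset$records
  # reverse the reader labels
  rec$reader_id <- sprintf("R%d", 9 - as.integer(sub("R", "",
                                                     rec$reader_id)))
  relabeled <- parse_score_table(rec, warn_inconsistent = FALSE)
  for (metric in c("tau_b", "percent_overall")) {
    a <- interobserver_agreement(study$dataset, "HER2", "tma_core",
                                 "optical", metric = metric)
    b <- interobserver_agreement(relabeled, "HER2", "tma_core", "optical",
                                 metric = metric)
    expect_equal(a$point, b$point)
  }
})

test_that("intermodality agreement averages each reader against themselves", {
  # R1 agrees with themselves on 4/5 (80%), R2 on 3/5 (60%)
  ds <- make_dataset(list(
    R1 = list(optical = c(10, 30, 60, 90, 20),
              digital = c(10, 30, 60, 90, 60)),
    R2 = list(optical = c(10, 30, 60, 90, 20),
              digital = c(10, 80, 60, 20, 20))))
  est <- intermodality_agreement(ds, "HER2", "whole_slide",
                                 metric = "percent_overall")
  expect_equal(est$per_unit, c(R1 = 80, R2 = 60))
  expect_equal(est$point, 70)

  same <- make_dataset(list(R1 = list(optical = c(5, 40, 90),
                                      digital = c(5, 40, 90))))
  expect_equal(intermodality_agreement(same, "HER2", "whole_slide",
                                       metric = "tau_b")$point, 1)
})

test_that("a reader with no overlapping scored cases drops from the intermodality mean", {
  ds <- make_dataset(list(
    R1 = list(optical = c(10, 30, 60), digital = c(10, 30, 60)),
    R2 = list(optical = c(10, NA, NA), digital = c(NA, 30, 60))))
  est <- intermodality_agreement(ds, "HER2", "whole_slide",
                                 metric = "percent_overall")
  expect_equal(est$point, 100)
  expect_equal(est$n_units_defined, 1)
  expect_true(is.na(est$per_unit[["R2"]]))
})

test_that("identical modalities give a zero difference with a degenerate CI", {
  v <- list(R1 = c(5, 30, 55, 80), R2 = c(10, 35, 60, 85),
            R3 = c(2, 28, 50, 95))
  ds <- make_dataset(lapply(v, function(x) list(optical = x, digital = x)))
  est <- agreement_difference(ds, "HER2", "whole_slide", metric = "tau_b",
                              boot = bootstrap_config(B = 200, seed = 9))
  expect_equal(est$point, 0)
  expect_equal(est$ci_low, 0)
  expect_equal(est$ci_high, 0)
})

test_that("injected digital-only noise drives the difference positive across seeds", {
  diffs <- vapply(1:60, function(s) {
    cfg_o <- noiseless_config("HER2", c(tma_core = 40), seed = 1000 + s)
    clean <- generate_study(cfg_o)$dataset
    rec <- clean$records
    dig <- rec$modality == "digital"
    set.seed(2000 + s)
    noisy <- pmin(100L, pmax(0L, rec$continuous_score[dig] +
                               as.integer(round(rnorm(sum(dig), 0, 15)))))
    rec$continuous_score[dig] <- noisy
    rec$categorical_score[dig] <- categorize_continuous(noisy, her2_scale())
    ds <- parse_score_table(rec, warn_inconsistent = FALSE)
    agreement_difference(ds, "HER2", "tma_core", metric = "tau_b")$point
  }, numeric(1))
  expect_true(mean(diffs > 0) > 0.95)
  expect_gt(mean(diffs), 0)
})

test_that("mean interobserver tau-b decreases as reader noise grows", {
  grid <- c(0, 5, 15, 30)
  means <- vapply(grid, function(noise) {
    vals <- vapply(1:40, function(s) {
      ds <- generate_study(synthetic_study_config(
        "HER2", n_cases = c(tma_core = 30), reader_bias_sd = 5,
        reader_noise_sd = noise, defer_rate_base = 0,
        inadequate_case_fraction = 0, seed = 3000 + s))$dataset
      interobserver_agreement(ds, "HER2", "tma_core", "optical",
                              metric = "tau_b")$point
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("the report covers every stratum with CIs and marks Ki-67 categorical tau-b", {
  full <- generate_full_study(seed = 5)
  report <- build_report(full$dataset, bootstrap_config(B = 50, seed = 11))
  expect_s3_class(report, "study_report")
  expect_length(report$strata, 4)
  for (s in report$strata) {
    tc <- s$interobserver$tau_b_continuous
    expect_true(tc$optical$ci_low <= tc$optical$point)
    expect_true(tc$optical$ci_high >= tc$optical$point)
    expect_equal(s$accounting$possible_per_modality,
                 s$n_readers * s$n_cases_retained)
    if (s$biomarker == "Ki67") {
      expect_equal(s$interobserver$tau_b_categorical$status, "not_reported")
      expect_equal(s$intermodality$tau_b_categorical$status, "not_reported")
    } else {
      expect_s3_class(s$interobserver$tau_b_categorical$optical,
                      "agreement_estimate")
    }
    expect_named(s$interobserver$percent_category,
                 full$dataset$scales[[s$biomarker]]$categories)
  }
})

test_that("report files land on disk with the expected shapes", {
  full <- generate_full_study(seed = 6)
  out <- withr::local_tempdir()
  report <- build_report(full$dataset, bootstrap_config(B = 20, seed = 3))
  write_report(report, out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "exclusions.json")))
  expect_true(file.exists(file.path(out, "run.log")))
  tabs <- list.files(file.path(out, "tables"))
  expect_setequal(tabs, c(
    "HER2_interobserver_tau.csv", "HER2_interobserver_pa.csv",
    "HER2_intermodality_tau.csv", "HER2_intermodality_pa.csv",
    "Ki67_interobserver_tau.csv", "Ki67_interobserver_pa.csv",
    "Ki67_intermodality_tau.csv", "Ki67_intermodality_pa.csv"))
  io_tau <- utils::read.csv(file.path(out, "tables",
                                      "HER2_interobserver_tau.csv"))
  expect_true(all(c("optical", "digital", "difference") %in%
                    names(io_tau)))
  parsed <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(parsed$meta$B, 20)
})
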