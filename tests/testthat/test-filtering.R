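# 8 readers, 6 cases; case C1 deferred by `n_defer` readers in optical
defer_study <- function(n_defer, n_readers = 8, n_cases = 6) {
  base <- seq(5, by = 15, length.out = n_cases)
  scores <- list()
  for (r in seq_len(n_readers)) {
    v <- base
    if (r <= n_defer) v[1] <- NA
    scores[[sprintf("R%d", r)]] <- list(optical = v, digital = base)
  }
  make_dataset(scores)
}

test_that("a case goes only when strictly more than half the readers defer it", {
  fx5 <- exclude_majority_deferred(defer_study(5))
  expect_equal(fx5$report$excluded_cases$case_id, "C1")
  expect_equal(fx5$report$excluded_cases$deferral_count, 5)
  expect_equal(fx5$dataset$cases[["HER2.whole_slide"]],
               sprintf("C%d", 2:6))

  fx4 <- exclude_majority_deferred(defer_study(4))
  expect_equal(nrow(fx4$report$excluded_cases), 0)
  expect_equal(length(fx4$dataset$cases[["HER2.whole_slide"]]), 6)

  fx0 <- exclude_majority_deferred(defer_study(0))
  expect_equal(nrow(fx0$report$excluded_cases), 0)
  expect_equal(fx0$dataset$records, defer_study(0)$records)
})

test_that("majority-deferral exclusion is idempotent", {
  once <- exclude_majority_deferred(defer_study(6))
  twice <- exclude_majority_deferred(once$dataset)
  expect_equal(twice$dataset$records, once$dataset$records)
  expect_equal(nrow(twice$report$excluded_cases), 0)
})

test_that("pooled and per-modality majority rules differ as designed", {
  # C1: 3 readers defer in optical, 2 different readers defer in digital
  base <- seq(5, by = 15, length.out = 6)
  scores <- list()
  for (r in 1:8) {
    opt <- base; dig <- base
    if (r <= 3) opt[1] <- NA
    if (r %in% 4:5) dig[1] <- NA
    scores[[sprintf("R%d", r)]] <- list(optical = opt, digital = dig)
  }
  ds <- make_dataset(scores)
  pooled <- exclude_majority_deferred(ds, pool_modalities = TRUE)
  expect_equal(pooled$report$excluded_cases$case_id, "C1") # 5 distinct readers
  per_mod <- exclude_majority_deferred(ds, pool_modalities = FALSE)
  expect_equal(nrow(per_mod$report$excluded_cases), 0)     # max 3 per modality
})

test_that("deferral accounting reports readers x retained cases as possible", {
  fx <- exclude_majority_deferred(defer_study(5))
  acct <- fx$report$deferral_counts
  expect_true(all(acct$possible == 8 * 5))
  opt <- acct[acct$modality == "optical", ]
  expect_equal(opt$deferred, 0)  # the only deferrals sat on the excluded case
  expect_true(all(acct$deferred <= acct$possible))
})

test_that("insufficient Ki-67 scores are masked to missing, HER2 untouched", {
  rows <- rbind(
    data.frame(reader_id = "R1", case_id = c("K1", "K2"),
               modality = "optical", biomarker = "Ki67",
               specimen_format = "tma_core",
               categorical_score = c("positive", "negative"),
               continuous_score = c(40L, 5L), deferred = FALSE,
               sufficient_cells = c(FALSE, TRUE), stringsAsFactors = FALSE),
    data.frame(reader_id = "R1", case_id = "H1", modality = "optical",
               biomarker = "HER2", specimen_format = "tma_core",
               categorical_score = "2+", continuous_score = 60L,
               deferred = FALSE, sufficient_cells = FALSE,
               stringsAsFactors = FALSE))
  ds <- apply_sufficiency_rule(parse_score_table(rows))
  rec <- ds$records
  expect_true(is.na(rec$continuous_score[rec$case_id == "K1"]))
  expect_true(is.na(rec$categorical_score[rec$case_id == "K1"]))
  expect_equal(rec$continuous_score[rec$case_id == "K2"], 5L)
  expect_equal(rec$continuous_score[rec$case_id == "H1"], 60L)
  # all-sufficient dataset: identity
  rows2 <- rows
  rows2$sufficient_cells <- TRUE
  ds2 <- parse_score_table(rows2)
  expect_equal(apply_sufficiency_rule(ds2)$records, ds2$records)
})

test_that("pairwise alignment keeps exactly the jointly scored cases", {
  ds <- make_dataset(list(
    R1 = list(optical = c(1, 2, NA)),
    R2 = list(optical = c(1, NA, 3))))
  pc <- pairwise_complete(ds, list(reader = "R1", modality = "optical"),
                          list(reader = "R2", modality = "optical"),
                          "HER2", "whole_slide")
  expect_equal(pc$x, 1)
  expect_equal(pc$y, 1)
  expect_equal(pc$cases, "C1")
  expect_false(pc$ok)

  # symmetry: swapping units swaps the vectors, same case list
  pc2 <- pairwise_complete(ds, list(reader = "R2", modality = "optical"),
                           list(reader = "R1", modality = "optical"),
                           "HER2", "whole_slide")
  expect_equal(pc2$x, pc$y)
  expect_equal(pc2$y, pc$x)
  expect_equal(pc2$cases, pc$cases)
})

test_that("disjoint missingness yields a flagged empty alignment", {
  ds <- make_dataset(list(
    R1 = list(optical = c(1, NA, 3, NA)),
    R2 = list(optical = c(NA, 2, NA, 4))))
  pc <- pairwise_complete(ds, list(reader = "R1", modality = "optical"),
                          list(reader = "R2", modality = "optical"),
                          "HER2", "whole_slide")
  expect_equal(pc$n, 0)
  expect_false(pc$ok)
  expect_length(pc$x, 0)
})

test_that("complete data aligns every case in order", {
  ds <- make_dataset(list(
    R1 = list(optical = seq(2, by = 4, length.out = 25)),
    R2 = list(optical = seq(3, by = 4, length.out = 25))))
  pc <- pairwise_complete(ds, list(reader = "R1", modality = "optical"),
                          list(reader = "R2", modality = "optical"),
                          "HER2", "whole_slide")
  expect_equal(pc$n, 25)
  expect_equal(pc$cases, sprintf("C%d", 1:25))
})
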