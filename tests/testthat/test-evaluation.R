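strata <- c("AD", "nonAD_thoracalgia", "nonAD_no_thoracalgia")

## build a confusion directly from target cell counts
conf_from_counts <- function(TP, FN, TN_t, FP_t, TN_nt, FP_nt) {
  labels <- c(rep(1L, TP + FN), rep(0L, TN_t + FP_t + TN_nt + FP_nt))
  stratum <- c(rep("AD", TP + FN),
               rep("nonAD_thoracalgia", TN_t + FP_t),
               rep("nonAD_no_thoracalgia", TN_nt + FP_nt))
  preds <- c(rep(1L, TP), rep(0L, FN),
             rep(0L, TN_t), rep(1L, FP_t),
             rep(0L, TN_nt), rep(1L, FP_nt))
  tally(preds, labels, stratum)
}

test_that("tally partitions every row into the six cells", {
  cf <- conf_from_counts(1, 1, 1, 1, 1, 1)
  expect_equal(unlist(cf[c("TP", "FN", "TN_t", "FP_t", "TN_nt", "FP_nt")]),
               c(TP = 1, FN = 1, TN_t = 1, FP_t = 1, TN_nt = 1, FP_nt = 1))
  # perfect predictions empty the error cells
  cf <- conf_from_counts(5, 0, 7, 0, 11, 0)
  expect_equal(cf$FN + cf$FP_t + cf$FP_nt, 0)
  # all-positive predictions empty the true-negative cells
  cf <- conf_from_counts(5, 0, 0, 7, 0, 11)
  expect_equal(cf$TN_t + cf$TN_nt, 0)
})

test_that("tally validates shapes and stratum consistency", {
  expect_error(tally(c(1, 0), c(1, 0, 0), rep("AD", 3)), "equal length")
  expect_error(tally(c(1, 0), c(1, 0), c("AD", "AD")), "inconsistent")
  expect_error(tally(c(1, 0), c(1, 0), c("AD", "elsewhere")), "stratum")
})

test_that("metrics reproduce hand-computed ratios exactly", {
  # accuracy: TP=9, TN=71, FP=12, FN=8 -> 80 / 100
  cf <- conf_from_counts(9, 8, 40, 5, 31, 7)
  expect_equal(accuracy(cf), 80)
  # recall: 73 / (73 + 17)
  cf <- conf_from_counts(73, 17, 1, 0, 1, 0)
  expect_equal(recall(cf), 100 * 73 / 90)
  expect_equal(round(recall(cf), 2), 81.11)
  # stratified error rates
  cf <- conf_from_counts(1, 0, 101, 24, 50, 0)
  expect_equal(error_rate_t(cf), 19.2)
  expect_equal(error_rate_nt(cf), 0)
})

test_that("accuracy from stratified cells equals pooled accuracy", {
  withr::with_seed(8, {
    for (i in 1:20) {
      cells <- rpois(6, 10)
      if (sum(cells) == 0) cells[1] <- 1
      cf <- do.call(conf_from_counts, as.list(cells))
      TN <- cf$TN_t + cf$TN_nt
      FP <- cf$FP_t + cf$FP_nt
      pooled <- 100 * (cf$TP + TN) / (cf$TP + TN + FP + cf$FN)
      expect_equal(accuracy(cf), pooled)
      for (m in list(accuracy(cf), recall(cf), error_rate_t(cf),
                     error_rate_nt(cf))) {
        if (!is.na(m)) { expect_gte(m, 0); expect_lte(m, 100) }
      }
    }
  })
})

test_that("empty denominators give NA markers, never zero", {
  cf <- conf_from_counts(0, 0, 3, 1, 4, 0)
  expect_true(is.na(recall(cf)))
  cf <- conf_from_counts(2, 1, 0, 0, 4, 0)
  expect_true(is.na(error_rate_t(cf)))
  expect_error(accuracy(structure(list(TP = 0, FN = 0, TN_t = 0, FP_t = 0,
                                       TN_nt = 0, FP_nt = 0),
                                  class = "stratified_confusion")),
               "empty")
})

test_that("recall ignores non-AD rows; ER_t ignores AD and no-pain rows", {
  base <- conf_from_counts(6, 4, 10, 5, 20, 2)
  more_neg <- conf_from_counts(6, 4, 30, 15, 99, 1)
  expect_equal(recall(base), recall(more_neg))
  a <- conf_from_counts(6, 4, 10, 5, 20, 2)
  b <- conf_from_counts(1, 9, 10, 5, 77, 30)
  expect_equal(error_rate_t(a), error_rate_t(b))
})

test_that("stratified split preserves strata and is reproducible", {
  co <- generate_cohort(n_minority = 40, imbalance_ratio = 10, seed = 15)
  sp <- stratified_split(co, 0.75, seed = 3)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(co))
  expect_equal(sum(sp$train$label == 1L), 30)
  tr_tab <- table(sp$train$stratum) / table(co$stratum)
  expect_true(all(abs(tr_tab - 0.75) < 0.05))
  sp2 <- stratified_split(co, 0.75, seed = 3)
  expect_identical(as.data.frame(sp$train), as.data.frame(sp2$train))
  expect_error(stratified_split(co, 1.2), "prop")
})

test_that("the comparison harness reports all methods in range, reproducibly", {
  co <- generate_cohort(n_minority = 60, imbalance_ratio = 12, seed = 16)
  rep1 <- compare_models(co, methods = c("lda", "dt", "rs_easyensemble"),
                         seeds = 1:2, rounds = 5, m = 4)
  expect_equal(rep1$method, c("lda", "dt", "rs_easyensemble"))
  for (col in c("accuracy", "recall", "er_t", "er_nt")) {
    v <- rep1[[col]][!is.na(rep1[[col]])]
    expect_true(all(v >= 0 & v <= 100))
  }
  rep2 <- compare_models(co, methods = c("lda", "dt", "rs_easyensemble"),
                         seeds = 1:2, rounds = 5, m = 4)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
})

test_that("undersampling ensemble recall dominates LDA on imbalanced data", {
  co <- generate_cohort(n_minority = 80, imbalance_ratio = 15, seed = 17)
  rep <- compare_models(co, methods = c("lda", "rs_easyensemble"),
                        seeds = 1:3, rounds = 10, m = 6)
  expect_gte(rep$recall[rep$method == "rs_easyensemble"],
             rep$recall[rep$method == "lda"])
})

test_that("a failing method yields a marked row and the run continues", {
  co <- generate_cohort(n_minority = 60, imbalance_ratio = 12, seed = 18)
  expect_warning(
    rep <- compare_models(co, methods = c("rs_easyensemble", "lda"),
                          seeds = 1, rounds = 5, m = 3),  # odd m fails
    "failed")
  expect_true(rep$failed[rep$method == "rs_easyensemble"])
  expect_false(rep$failed[rep$method == "lda"])
})
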