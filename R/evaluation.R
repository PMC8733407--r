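#' Stratified confusion counts
#'
#' Cross-tabulates predictions against the truth with the non-AD class split
#' by chest-pain stratum, the accounting scheme behind the study's stratified
#' error rates: `TP`/`FN` over AD rows, `TN_t`/`FP_t` over non-AD rows with
#' thoracalgia, `TN_nt`/`FP_nt` over non-AD rows without. The six cells
#' always partition the evaluated rows exactly.
#'
#' @param predictions 0/1 predicted labels.
#' @param labels 0/1 true labels.
#' @param stratum three-level stratum vector (`"AD"`, `"nonAD_thoracalgia"`,
#'   `"nonAD_no_thoracalgia"`), consistent with `labels`.
#' @return object of class `stratified_confusion`.
#' @examples
#' co <- generate_cohort(n_minority = 10, imbalance_ratio = 4, seed = 3)
#' tally(rep(1, nrow(co)), co$label, co$stratum)
#' @export
tally <- function(predictions, labels, stratum) {
  predictions <- as_label01(predictions)
  labels <- as_label01(labels)
  if (length(predictions) != length(labels) ||
      length(labels) != length(stratum))
    stopf("predictions, labels and stratum must have equal length")
  stratum <- factor(as.character(stratum), levels = stratum_levels())
  if (any(is.na(stratum)))
    stopf("unknown stratum values; expected %s",
          paste(stratum_levels(), collapse = ", "))
  if (any((stratum == "AD") != (labels == 1L)))
    stopf("stratum is inconsistent with labels")
  ad <- stratum == "AD"
  th <- stratum == "nonAD_thoracalgia"
  nt <- stratum == "nonAD_no_thoracalgia"
  structure(list(
    TP = sum(ad & predictions == 1L),
    FN = sum(ad & predictions == 0L),
    TN_t = sum(th & predictions == 0L),
    FP_t = sum(th & predictions == 1L),
    TN_nt = sum(nt & predictions == 0L),
    FP_nt = sum(nt & predictions == 1L)),
    class = "stratified_confusion")
}

#' @export
print.stratified_confusion <- function(x, ...) {
  cat("Stratified confusion counts\n")
  cat(sprintf("  AD:                    TP = %d, FN = %d\n", x$TP, x$FN))
  cat(sprintf("  non-AD, thoracalgia:   TN_t = %d, FP_t = %d\n",
              x$TN_t, x$FP_t))
  cat(sprintf("  non-AD, no chest pain: TN_nt = %d, FP_nt = %d\n",
              x$TN_nt, x$FP_nt))
  invisible(x)
}

conf_total <- function(c)
  c$TP + c$FN + c$TN_t + c$FP_t + c$TN_nt + c$FP_nt

ratio_pct <- function(num, den) {
  if (den == 0) NA_real_ else 100 * num / den
}

#' Diagnostic performance metrics, in percent
#'
#' The four study metrics on a [tally()] result: overall `accuracy()`
#' ((TP + TN) / all), `recall()` (TP / (TP + FN), the study's priority
#' metric), and the stratified false-positive rates `error_rate_t()`
#' (FP_t / (TN_t + FP_t), among non-AD patients with chest pain) and
#' `error_rate_nt()` (the same among non-AD patients without). A metric
#' whose denominator is empty returns `NA` ("not applicable"), never 0.
#'
#' @param confusion a `stratified_confusion`.
#' @return a percentage in [0, 100], or `NA` for an empty denominator.
#' @examples
#' co <- generate_cohort(n_minority = 10, imbalance_ratio = 4, seed = 3)
#' cf <- tally(co$label, co$label, co$stratum)  # perfect predictions
#' c(accuracy(cf), recall(cf), error_rate_t(cf), error_rate_nt(cf))
#' @export
accuracy <- function(confusion) {
  total <- conf_total(confusion)
  if (total == 0) stopf("undefined metric: empty confusion")
  100 * (confusion$TP + confusion$TN_t + confusion$TN_nt) / total
}

#' @rdname accuracy
#' @export
recall <- function(confusion)
  ratio_pct(confusion$TP, confusion$TP + confusion$FN)

#' @rdname accuracy
#' @export
error_rate_t <- function(confusion)
  ratio_pct(confusion$FP_t, confusion$TN_t + confusion$FP_t)

#' @rdname accuracy
#' @export
error_rate_nt <- function(confusion)
  ratio_pct(confusion$FP_nt, confusion$TN_nt + confusion$FP_nt)

#' Stratified train/test split of a cohort
#'
#' Splits rows into a training and a test portion while preserving the
#' three-level stratum composition; seed-controlled and reproducible.
#'
#' @param cohort an `ad_cohort` data.frame.
#' @param prop training fraction (default 0.75).
#' @param seed integer seed.
#' @return list with `train` and `test` cohort data frames.
#' @export
stratified_split <- function(cohort, prop = 0.75, seed = 1) {
  if (!is.numeric(prop) || prop <= 0 || prop >= 1)
    stopf("`prop` must lie strictly between 0 and 1")
  idx <- with_seed(seed, split_indices(cohort$stratum, prop))
  list(train = cohort[idx$first, , drop = FALSE],
       test = cohort[idx$second, , drop = FALSE])
}

#' Compare the study methods on one cohort
#'
#' For each requested method and seed: make a stratified train/test split,
#' fit on the training portion, predict the test portion, and tabulate the
#' four metrics. Per-method metrics are averaged over seeds. A method that
#' fails to train is reported as a row of `NA`s with the error message
#' attached, and the run continues.
#'
#' @param cohort an `ad_cohort` with all three strata present.
#' @param methods character vector of [fit_method()] names, or `"all"` for
#'   the five study methods.
#' @param split training fraction for the stratified split.
#' @param seeds integer vector of seeds (split and fit share each seed).
#' @param ... extra arguments passed to every `fit_method()` call.
#' @return data.frame of class `model_comparison`: one row per method with
#'   `accuracy`, `recall`, `er_t`, `er_nt` (percent, seed-averaged) and
#'   `failed`; attributes record the split policy and seeds.
#' @export
compare_models <- function(cohort,
                           methods = c("lda", "bp", "dt", "svm",
                                       "rs_easyensemble"),
                           split = 0.75, seeds = 1, ...) {
  if (identical(methods, "all"))
    methods <- c("lda", "bp", "dt", "svm", "rs_easyensemble")
  if (nlevels(droplevels(factor(cohort$stratum))) < 3)
    stopf("cohort must contain all three strata")
  rows <- lapply(methods, function(m) {
    per_seed <- lapply(seeds, function(s) {
      sp <- stratified_split(cohort, prop = split, seed = s)
      tryCatch({
        fit <- fit_method(method = m, cohort = sp$train, seed = s, ...)
        pred <- stats::predict(fit, sp$test)
        cf <- tally(pred, sp$test$label, sp$test$stratum)
        list(ok = TRUE,
             metrics = c(accuracy = accuracy(cf), recall = recall(cf),
                         er_t = error_rate_t(cf),
                         er_nt = error_rate_nt(cf)))
      }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    })
    ok <- vapply(per_seed, `[[`, TRUE, "ok")
    if (!any(ok)) {
      warning(sprintf("method '%s' failed: %s", m, per_seed[[1]]$msg),
              call. = FALSE)
      return(data.frame(method = m, accuracy = NA_real_, recall = NA_real_,
                        er_t = NA_real_, er_nt = NA_real_, failed = TRUE,
                        stringsAsFactors = FALSE))
    }
    mt <- rowMeans(vapply(per_seed[ok], `[[`, numeric(4), "metrics"),
                   na.rm = TRUE)
    data.frame(method = m, accuracy = mt[["accuracy"]],
               recall = mt[["recall"]], er_t = mt[["er_t"]],
               er_nt = mt[["er_nt"]], failed = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, split = split, seeds = seeds,
            class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (stratified %.0f/%.0f split; seeds: %s)\n",
              100 * attr(x, "split"), 100 * (1 - attr(x, "split")),
              paste(attr(x, "seeds"), collapse = ", ")))
  fmt <- function(v) ifelse(is.na(v), "n/a", sprintf("%.2f%%", v))
  df <- data.frame(method = x$method, accuracy = fmt(x$accuracy),
                   recall = fmt(x$recall), er_t = fmt(x$er_t),
                   er_nt = fmt(x$er_nt),
                   stringsAsFactors = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
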