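#' Two-sample t statistic from summary data
#'
#' Computes the two-sample t statistic for an index reported only as
#' mean +/- SD per class, as in published cohort tables. The default is the
#' Welch (unequal-variance) statistic with Welch-Satterthwaite degrees of
#' freedom; `var_equal = TRUE` gives the pooled-variance statistic with
#' `n_ad + n_non - 2` degrees of freedom. The sign convention is
#' non-AD minus AD, so indexes elevated in AD patients yield negative t.
#'
#' @param mean_ad,sd_ad,n_ad AD-class mean, SD and sample size.
#' @param mean_non,sd_non,n_non non-AD-class mean, SD and sample size.
#' @param var_equal use the pooled-variance statistic instead of Welch.
#' @return list with elements `statistic` and `df`.
#' @examples
#' # heart rate: 81.74 +/- 13.87 (n = 802) vs 78.73 +/- 14.20 (n = 52411)
#' welch_t_from_summary(81.74, 13.87, 802, 78.73, 14.20, 52411)
#' @export
welch_t_from_summary <- function(mean_ad, sd_ad, n_ad,
                                 mean_non, sd_non, n_non,
                                 var_equal = FALSE) {
  if (n_ad < 2 || n_non < 2) stopf("both groups need n >= 2")
  if (sd_ad < 0 || sd_non < 0) stopf("standard deviations must be >= 0")
  if (sd_ad == 0 && sd_non == 0)
    stopf("degenerate variance: both group SDs are zero")
  if (var_equal) {
    sp2 <- ((n_ad - 1) * sd_ad^2 + (n_non - 1) * sd_non^2) /
      (n_ad + n_non - 2)
    se <- sqrt(sp2 * (1 / n_ad + 1 / n_non))
    df <- n_ad + n_non - 2
  } else {
    v1 <- sd_ad^2 / n_ad
    v0 <- sd_non^2 / n_non
    se <- sqrt(v1 + v0)
    df <- (v1 + v0)^2 / (v1^2 / (n_ad - 1) + v0^2 / (n_non - 1))
  }
  list(statistic = (mean_non - mean_ad) / se, df = df)
}

#' Pearson chi-square statistic for a contingency table
#'
#' Plain Pearson chi-square on an r x c count table, without continuity
#' correction (the convention needed to reproduce published 2 x 2 index
#' statistics). Degrees of freedom are (r-1)(c-1).
#'
#' @param counts numeric matrix of nonnegative counts.
#' @return list with elements `statistic` and `df`.
#' @examples
#' pearson_chi2(rbind(c(574, 29994), c(228, 22417)))  # gender vs outcome
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("degenerate table: a row or column margin is zero")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter))
}

#' Tail p-value for a screening statistic
#'
#' @param statistic observed statistic.
#' @param df degrees of freedom (> 0).
#' @param family `"t_two_sided"` for a two-sided Student-t tail,
#'   `"chi2_upper"` for the upper chi-square tail.
#' @return p-value in [0, 1].
#' @export
screening_p_value <- function(statistic, df,
                              family = c("t_two_sided", "chi2_upper")) {
  family <- match.arg(family)
  if (!is.numeric(df) || df <= 0) stopf("`df` must be > 0")
  switch(family,
         t_two_sided = 2 * stats::pt(-abs(statistic), df),
         chi2_upper = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Univariate index screening of a cohort
#'
#' Reproduces the study's index-screening stage on a raw cohort: each
#' continuous feature is tested by a two-sample t test (Welch by default),
#' each binary/categorical feature by a Pearson chi-square test on its
#' outcome contingency table (no continuity correction), and features with
#' p <= `alpha` are flagged as selected. A feature constant in both classes
#' is reported with p = 1 and a warning rather than an error.
#'
#' @param cohort an `ad_cohort` (or data.frame with a `label` column).
#' @param alpha selection threshold on the p-value (the study used 0.001).
#' @param test `"welch"` or `"pooled"` variance handling for continuous
#'   features.
#' @return data.frame of class `ad_screening` with one row per feature:
#'   `index`, `kind`, `statistic`, `df`, `p_value`, `selected`, in input
#'   column order.
#' @export
screen_cohort <- function(cohort, alpha = 0.001,
                          test = c("welch", "pooled")) {
  test <- match.arg(test)
  y <- as_label01(cohort$label)
  if (sum(y == 1L) < 2 || sum(y == 0L) < 2)
    stopf("screening needs at least 2 samples per class")
  specs <- attr(cohort, "feature_specs")
  kinds <- impute_kinds(cohort, specs)
  feats <- names(kinds)

  rows <- lapply(feats, function(nm) {
    v <- cohort[[nm]]
    ok <- !is.na(v)
    vv <- v[ok]; yy <- y[ok]
    if (length(unique(vv)) < 2) {
      warning(sprintf("feature '%s' is constant; p set to 1", nm),
              call. = FALSE)
      return(data.frame(index = nm, kind = kinds[[nm]],
                        statistic = NA_real_, df = NA_real_, p_value = 1,
                        selected = FALSE, stringsAsFactors = FALSE))
    }
    if (kinds[[nm]] == "continuous") {
      ht <- stats::t.test(vv[yy == 0L], vv[yy == 1L],
                          var.equal = (test == "pooled"))
      data.frame(index = nm, kind = "continuous",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 selected = ht$p.value <= alpha, stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(vv), factor(yy, levels = c(1, 0)))
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(index = nm, kind = kinds[[nm]],
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 selected = ht$p.value <= alpha, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  structure(out, alpha = alpha, test = test,
            class = c("ad_screening", "data.frame"))
}

#' @export
print.ad_screening <- function(x, digits = 3, ...) {
  cat(sprintf("Index screening (%s t for continuous, alpha = %g): %d of %d selected\n",
              attr(x, "test"), attr(x, "alpha"), sum(x$selected), nrow(x)))
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, digits)
  df$df <- round(df$df, 1)
  df$p_value <- signif(df$p_value, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Screen published summary rows
#'
#' Applies [welch_t_from_summary()] / [pearson_chi2()] to a list of
#' [feature_spec()]s carrying published class-conditional summaries (counts
#' for discrete indexes, mean/SD for continuous ones), yielding the same
#' report layout as [screen_cohort()] without any raw data.
#'
#' @inheritParams screen_cohort
#' @param specs list of [feature_spec()]s, e.g. [builtin_cohort_specs()].
#' @param n_ad,n_non class sample sizes for continuous rows.
#' @export
screen_summary <- function(specs = builtin_cohort_specs(), alpha = 0.001,
                           test = c("welch", "pooled"),
                           n_ad = 802, n_non = 52411) {
  test <- match.arg(test)
  rows <- lapply(specs, function(s) {
    if (s$kind == "continuous") {
      r <- welch_t_from_summary(s$class1$mean, s$class1$sd, n_ad,
                                s$class0$mean, s$class0$sd, n_non,
                                var_equal = (test == "pooled"))
      p <- screening_p_value(r$statistic, r$df, "t_two_sided")
    } else {
      counts <- if (s$kind == "binary")
        rbind(c(s$class1$count, s$class0$count),
              c(s$class1$n - s$class1$count, s$class0$n - s$class0$count))
      else cbind(s$class1$counts, s$class0$counts)
      r <- pearson_chi2(counts)
      p <- screening_p_value(r$statistic, r$df, "chi2_upper")
    }
    data.frame(index = s$name, kind = s$kind, statistic = r$statistic,
               df = r$df, p_value = p, selected = p <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, alpha = alpha, test = test,
            class = c("ad_screening", "data.frame"))
}
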