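#' Synthetic imbalanced cohort tables
#'
#' [generate_cohort()] draws a synthetic clinical cohort with the
#' class-conditional marginal structure given by a list of
#' [feature_spec()]s: continuous indexes are class-conditional Gaussian,
#' yes/no indexes class-conditional Bernoulli, and multi-level indexes
#' class-conditional categorical draws. Features are generated independently
#' given the class — only marginal class-conditional moments are modelled.
#' Class sizes are fixed by design (`n_minority` AD rows and
#' `round(n_minority * imbalance_ratio)` non-AD rows), never drawn at random,
#' so every seed reproduces the requested imbalance exactly.
#'
#' The returned table carries a three-level `stratum` column used for
#' stratified error reporting: `"AD"` for minority rows, and non-AD rows are
#' split into `"nonAD_thoracalgia"` / `"nonAD_no_thoracalgia"` by their
#' chest-pain indicator.
#'
#' @param specs list of [feature_spec()] objects; defaults to the built-in
#'   published parameters ([builtin_cohort_specs()]).
#' @param n_minority number of AD (label 1) rows; the study cohort had 802.
#' @param imbalance_ratio majority:minority ratio (>= 1); the study cohort
#'   ratio was 52,411/802 ~ 65.35.
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @param missing_rate fraction of feature cells blanked completely at random.
#' @param thoracalgia_col name of the binary chest-pain column that defines
#'   the non-AD strata.
#' @return a data.frame of class `ad_cohort` with one column per feature plus
#'   `label` (integer 0/1) and `stratum` (factor); attributes `feature_specs`
#'   and `seed` record the generating design.
#' @examples
#' co <- generate_cohort(n_minority = 20, imbalance_ratio = 5, seed = 1)
#' table(co$label)
#' @export
generate_cohort <- function(specs = builtin_cohort_specs(),
                            n_minority = 802,
                            imbalance_ratio = 65.35,
                            seed = 1,
                            missing_rate = 0,
                            thoracalgia_col = "thoracalgia") {
  if (!is_count(n_minority, min = 1))
    stopf("`n_minority` must be a positive integer")
  if (!is.numeric(imbalance_ratio) || imbalance_ratio < 1)
    stopf("`imbalance_ratio` must be >= 1")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate > 1)
    stopf("`missing_rate` must lie in [0, 1]")
  n_majority <- round(n_minority * imbalance_ratio)
  n <- n_minority + n_majority
  label <- c(rep(1L, n_minority), rep(0L, n_majority))

  cols <- with_seed(seed, {
    out <- lapply(specs, function(s) {
      draw <- function(p, m) {
        switch(s$kind,
          continuous = stats::rnorm(m, p$mean, p$sd),
          binary = stats::rbinom(m, 1L, p$prevalence),
          categorical = {
            vals <- p$values %||% seq_along(p$prob) - 1
            vals[sample.int(length(p$prob), m, replace = TRUE,
                            prob = p$prob)]
          })
      }
      c(draw(s$class1, n_minority), draw(s$class0, n_majority))
    })
    names(out) <- vapply(specs, `[[`, "", "name")
    if (missing_rate > 0) {
      d <- length(out)
      miss <- matrix(stats::runif(n * d) < missing_rate, nrow = n)
      for (j in seq_len(d)) out[[j]][miss[, j]] <- NA_real_
    }
    out
  })

  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  df$label <- label
  thor <- if (thoracalgia_col %in% names(df)) df[[thoracalgia_col]]
          else rep(0, n)
  df$stratum <- derive_stratum(label, thor)
  as_ad_cohort(df, feature_specs = specs, seed = as.integer(seed))
}

#' @rdname generate_cohort
#' @param label integer 0/1 outcome vector.
#' @param thoracalgia binary chest-pain indicator (NA treated as 0).
#' @export
derive_stratum <- function(label, thoracalgia) {
  thor <- ifelse(is.na(thoracalgia), 0, thoracalgia)
  out <- ifelse(label == 1L, "AD",
                ifelse(thor == 1, "nonAD_thoracalgia", "nonAD_no_thoracalgia"))
  factor(out, levels = stratum_levels())
}

stratum_levels <- function()
  c("AD", "nonAD_thoracalgia", "nonAD_no_thoracalgia")

as_ad_cohort <- function(df, feature_specs = NULL, seed = NA_integer_) {
  stopifnot("label" %in% names(df), "stratum" %in% names(df))
  df$label <- as_label01(df$label)
  df$stratum <- factor(as.character(df$stratum), levels = stratum_levels())
  if (any(is.na(df$stratum)))
    stopf("`stratum` must take values %s",
          paste(stratum_levels(), collapse = ", "))
  if (any((df$stratum == "AD") != (df$label == 1L)))
    stopf("stratum 'AD' must coincide with label 1")
  structure(df, feature_specs = feature_specs, seed = seed,
            class = c("ad_cohort", "data.frame"))
}

#' Extract the feature matrix of a cohort
#'
#' Drops the `label` and `stratum` columns and returns a numeric matrix.
#'
#' @param cohort an `ad_cohort` (or any data.frame with those columns).
#' @export
cohort_features <- function(cohort) as_feature_matrix(cohort)

#' @export
print.ad_cohort <- function(x, ...) {
  d <- ncol(x) - 2L
  cat(sprintf("<ad_cohort: %d rows, %d features; %d AD / %d non-AD>\n",
              nrow(x), d, sum(x$label == 1L), sum(x$label == 0L)))
  print(table(stratum = x$stratum))
  invisible(x)
}

#' Impute missing feature cells
#'
#' Continuous columns get their observed column median; binary and
#' categorical columns their observed mode (smallest value on ties, so an
#' all-else-equal 0/1 column imputes 0). `label` and `stratum` are never
#' touched. A column with no observed value cannot be imputed and raises an
#' error naming it.
#'
#' @param cohort an `ad_cohort` data.frame.
#' @return the cohort with no missing feature cells.
#' @export
impute_missing <- function(cohort) {
  specs <- attr(cohort, "feature_specs")
  kinds <- impute_kinds(cohort, specs)
  for (nm in names(kinds)) {
    v <- cohort[[nm]]
    if (!anyNA(v)) next
    obs <- v[!is.na(v)]
    if (!length(obs))
      stopf("column '%s' is entirely missing and cannot be imputed", nm)
    fill <- if (kinds[[nm]] == "continuous") stats::median(obs) else {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])  # which.max: first = smallest
    }
    v[is.na(v)] <- fill
    cohort[[nm]] <- v
  }
  cohort
}

## continuous vs discrete per feature column, from specs when available,
## otherwise guessed from the observed values
impute_kinds <- function(cohort, specs) {
  feats <- setdiff(names(cohort), c("label", "stratum"))
  kinds <- stats::setNames(rep("continuous", length(feats)), feats)
  if (!is.null(specs)) {
    for (s in specs)
      if (s$name %in% feats) kinds[[s$name]] <- s$kind
  } else {
    for (nm in feats) {
      v <- cohort[[nm]]
      u <- unique(v[!is.na(v)])
      if (length(u) <= 3 && all(u == round(u))) kinds[[nm]] <- "binary"
    }
  }
  kinds
}
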