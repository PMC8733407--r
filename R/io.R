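#' Read and write cohort tables as CSV
#'
#' Cohorts travel as plain comma-separated files with a header row: one
#' numeric column per feature plus `label` (0/1) and optionally `stratum`.
#' When `stratum` is absent it is derived from the chest-pain column via the
#' cohort invariant (label 1 -> `"AD"`; label 0 split by thoracalgia).
#' Writing also emits a sidecar key-value file `<path>.meta` recording the
#' seed and class counts, and `<path>.specs.csv` with the generating feature
#' specs when the cohort carries them; a write/read round trip reproduces
#' values and column order exactly.
#'
#' @param path CSV file path.
#' @param cohort an `ad_cohort` data.frame.
#' @param thoracalgia_col column used to derive `stratum` when absent.
#' @param sidecar write the `.meta` / `.specs.csv` companions.
#' @return `read_cohort_csv()`: an `ad_cohort`; `write_cohort_csv()`: the
#'   path, invisibly.
#' @export
read_cohort_csv <- function(path, thoracalgia_col = "thoracalgia") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stopf("cannot parse '%s' as CSV: %s", path,
                              conditionMessage(e)))
  if (!nrow(df) || !ncol(df)) stopf("'%s' contains no data rows", path)
  if (!"label" %in% names(df))
    stopf("'%s' has no `label` column; found: %s", path,
          paste(names(df), collapse = ", "))
  feats <- setdiff(names(df), c("label", "stratum"))
  for (nm in feats) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA" & v != "")[1]
      if (!is.na(bad))
        stopf("non-numeric cell at row %d, column '%s': \"%s\"",
              bad, nm, v[bad])
      df[[nm]] <- num
    }
  }
  if (!"stratum" %in% names(df)) {
    if (!thoracalgia_col %in% names(df))
      stopf("no `stratum` column and no '%s' column to derive it from",
            thoracalgia_col)
    df$stratum <- derive_stratum(df$label, df[[thoracalgia_col]])
  }
  specs_path <- paste0(path, ".specs.csv")
  specs <- if (file.exists(specs_path)) read_feature_specs(specs_path)
           else NULL
  as_ad_cohort(df, feature_specs = specs)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path, sidecar = TRUE) {
  df <- as.data.frame(cohort)
  df$stratum <- as.character(df$stratum)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    specs <- attr(cohort, "feature_specs")
    meta <- c(
      sprintf("seed=%s", attr(cohort, "seed") %||% NA),
      sprintf("n=%d", nrow(df)),
      sprintf("n_minority=%d", sum(df$label == 1L)),
      sprintf("n_majority=%d", sum(df$label == 0L)),
      sprintf("specs=%s", if (is.null(specs)) "" else
        paste0(basename(path), ".specs.csv")))
    writeLines(meta, paste0(path, ".meta"))
    if (!is.null(specs)) write_feature_specs(specs, paste0(path,
                                                           ".specs.csv"))
  }
  invisible(path)
}

#' Save / load fitted models
#'
#' Thin serialization wrappers that tag the artifact with a format version;
#' loading a file whose version does not match fails loudly rather than
#' returning a silently incompatible model.
#'
#' @param model any fitted model from this package.
#' @param path file path (RDS).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "adensemble-model", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "adensemble-model"))
    stopf("'%s' is not a saved model file", path)
  if (!identical(obj$version, 1L))
    stopf("model file version %s not supported (expected 1)",
          toString(obj$version))
  obj$model
}
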