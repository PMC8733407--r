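#' Per-index class-conditional generative parameters
#'
#' A `feature_spec` describes one clinical index by its class-conditional
#' distribution: Gaussian (mean, sd) for continuous indexes, Bernoulli
#' (prevalence) for yes/no indexes, or a finite categorical distribution for
#' multi-level indexes such as smoking status (coded No = 0, Yes = 1,
#' Quit = 2). Class 1 is the aortic-dissection (AD, minority) class, class 0
#' the non-AD majority.
#'
#' @param name syntactic column name used in cohort tables.
#' @param feature_id integer index number (the study numbered features 1-80).
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param class1,class0 named lists of parameters for the AD and non-AD class:
#'   `mean`/`sd` for continuous, `prevalence` (with optional `count`, `n`) for
#'   binary, `prob` (with optional `counts` and `values`) for categorical.
#' @param units free-text measurement unit.
#' @param long_name display name, e.g. the printed index name.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(name, feature_id, kind, class1, class0,
                         units = "", long_name = name) {
  kind <- match.arg(kind, c("continuous", "binary", "categorical"))
  spec <- structure(
    list(name = name, feature_id = as.integer(feature_id), kind = kind,
         class1 = class1, class0 = class0, units = units,
         long_name = long_name),
    class = "feature_spec")
  validate_feature_spec(spec)
  spec
}

validate_feature_spec <- function(spec) {
  for (cl in c("class1", "class0")) {
    p <- spec[[cl]]
    switch(spec$kind,
      continuous = {
        if (!is.numeric(p$mean) || !is.numeric(p$sd) || p$sd < 0)
          stopf("feature '%s': continuous parameters need mean and sd >= 0",
                spec$name)
      },
      binary = {
        if (!is.numeric(p$prevalence) || p$prevalence < 0 || p$prevalence > 1)
          stopf("feature '%s': prevalence must lie in [0, 1]", spec$name)
      },
      categorical = {
        if (!is.numeric(p$prob) || any(p$prob < 0) ||
            abs(sum(p$prob) - 1) > 1e-9)
          stopf("feature '%s': categorical probabilities must sum to 1",
                spec$name)
      })
  }
  invisible(spec)
}

cont_spec <- function(name, id, m1, s1, m0, s0, units = "", long = name)
  feature_spec(name, id, "continuous",
               class1 = list(mean = m1, sd = s1),
               class0 = list(mean = m0, sd = s0),
               units = units, long_name = long)

bin_spec <- function(name, id, c1, p1, c0, p0, long = name,
                     n1 = 802L, n0 = 52411L)
  feature_spec(name, id, "binary",
               class1 = list(prevalence = p1 / 100, count = c1, n = n1),
               class0 = list(prevalence = p0 / 100, count = c0, n = n0),
               units = "0/1", long_name = long)

#' Built-in published index parameters for the AD study cohort
#'
#' Returns the screened clinical indexes with their published class-conditional
#' summary parameters: continuous indexes carry mean and SD per class
#' (AD, N = 802; non-AD, N = 52,411); yes/no indexes carry the published
#' prevalence (and the underlying counts, used for chi-square reproduction);
#' smoking status is a three-level categorical index (No = 0, Yes = 1,
#' Quit = 2). These parameters seed the synthetic cohort generator
#' ([generate_cohort()]) and the summary-statistic screening checks.
#'
#' The published table prints 40 index rows (counting smoking status once),
#' although its caption refers to 43 screened indexes; the transcription here
#' follows the printed rows.
#'
#' @return list of [feature_spec()] objects, in published row order.
#' @export
builtin_cohort_specs <- function() {
  sm1 <- c(296, 485, 21)     # AD: never / current / quit
  sm0 <- c(12293, 37121, 2997)
  specs <- list(
    cont_spec("age", 1, 55.57, 12.90, 62.56, 13.06, "years", "Age"),
    bin_spec("gender", 2, 574, 71.57, 29994, 57.23, "Gender (male = 1)"),
    bin_spec("thoracalgia", 3, 206, 25.79, 9460, 18.05, "Thoracalgia"),
    bin_spec("palpitation", 4, 63, 7.86, 6106, 11.65, "Palpitation"),
    bin_spec("dizziness_headache", 5, 62, 7.73, 7803, 14.89,
             "Dizziness or headache"),
    bin_spec("aortic_area_murmur", 6, 23, 2.87, 377, 0.72,
             "Aortic area murmur"),
    bin_spec("chest_trauma", 7, 11, 1.37, 206, 0.39, "Chest trauma"),
    feature_spec("smoking_status", 8, "categorical",
                 class1 = list(prob = c(36.91, 60.47, 2.62) / 100,
                               counts = sm1, values = c(0, 1, 2)),
                 class0 = list(prob = c(23.46, 70.83, 5.71) / 100,
                               counts = sm0, values = c(0, 1, 2)),
                 units = "0=never,1=current,2=quit",
                 long_name = "Smoking status"),
    cont_spec("time_of_smoking", 9, 10.22, 14.39, 7.34, 13.88, "years",
              "Time of smoking"),
    bin_spec("hypertension", 10, 530, 66.08, 31571, 60.24, "Hypertension"),
    bin_spec("diabetes", 11, 88, 10.97, 11910, 22.72, "Diabetes"),
    cont_spec("time_of_diabetes", 12, 0.85, 2.87, 1.82, 3.83, "years",
              "Time of diabetes"),
    cont_spec("heart_rate", 13, 81.74, 13.87, 78.73, 14.20, "beats/min",
              "Heart rate"),
    cont_spec("systolic_pressure", 14, 142.41, 26.71, 136.86, 21.90, "mmHg",
              "Systolic pressure"),
    cont_spec("diastolic_pressure", 15, 83.20, 16.59, 80.46, 13.01, "mmHg",
              "Diastolic pressure"),
    cont_spec("neutrophil_count", 16, 7.16, 4.08, 4.79, 3.47, "10^9/L",
              "Neutrophil granulocyte count"),
    cont_spec("neutrophil_pct", 17, 72.83, 10.79, 65.30, 12.09, "%",
              "Neutrophil percentage"),
    cont_spec("lymphocyte_pct", 18, 16.94, 9.10, 24.22, 10.44, "%",
              "Lymphocyte percentage"),
    cont_spec("lymphocyte_count", 19, 1.36, 0.60, 1.57, 2.03, "10^9/L",
              "Lymphocyte count"),
    cont_spec("mean_platelet_volume", 20, 8.93, 1.39, 9.36, 1.58, "fl",
              "Mean platelet volume"),
    cont_spec("total_protein", 21, 64.58, 7.06, 65.43, 8.04, "g/L",
              "Total protein"),
    cont_spec("albumin", 22, 37.08, 5.67, 38.61, 6.26, "g/L", "Albumin"),
    cont_spec("globulin", 23, 27.57, 5.19, 26.94, 5.32, "g/L", "Globulin"),
    cont_spec("ag_ratio", 24, 1.40, 0.36, 1.49, 0.37, "", "A/G"),
    cont_spec("total_bilirubin", 25, 16.19, 21.62, 13.20, 26.81, "umol/L",
              "Total bilirubin"),
    cont_spec("gpt", 26, 66.50, 296.27, 32.47, 108.73, "U/L",
              "Glutamic-pyruvic transaminase"),
    cont_spec("glycated_serum_protein", 27, 2.25, 0.62, 2.03, 0.73, "mmol/L",
              "Glycated serum protein"),
    cont_spec("lactic_dehydrogenase", 28, 322.03, 684.10, 236.51, 283.48,
              "U/L", "Lactic dehydrogenase"),
    cont_spec("myohemoglobin", 29, 72.69, 84.95, 57.60, 59.02, "ug/L",
              "Myohemoglobin"),
    cont_spec("potassium", 30, 3.83, 0.56, 3.97, 0.52, "mmol/L", "Potassium"),
    cont_spec("sodium", 31, 139.37, 4.28, 140.71, 3.79, "mmol/L", "Sodium"),
    cont_spec("chlorine", 32, 101.08, 4.95, 102.59, 4.62, "mmol/L",
              "Chlorine"),
    cont_spec("calcium", 33, 2.16, 0.16, 2.21, 0.18, "mmol/L", "Calcium"),
    cont_spec("prothrombin_pct", 34, 99.83, 18.59, 106.62, 17.36, "%",
              "Prothrombin percentage"),
    cont_spec("inr", 35, 1.06, 0.39, 1.01, 0.28, "",
              "International normalized ratio"),
    cont_spec("aptt", 36, 37.66, 11.29, 35.54, 9.68, "sec",
              "Activated partial thromboplastin time"),
    cont_spec("fibrinogen", 37, 4.44, 1.81, 3.77, 1.22, "g/L", "Fibrinogen"),
    cont_spec("d_dimer", 38, 1.37, 1.94, 0.97, 1.27, "mg/L", "D-dimer"),
    cont_spec("plasminogen_antigen", 39, 252.01, 24.57, 255.86, 27.68, "mg/L",
              "Plasma plasminogen antigen"),
    cont_spec("pt", 40, 13.57, 4.39, 13.02, 3.06, "sec", "Prothrombin time")
  )
  specs
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec %d: %s (%s)>\n", x$feature_id, x$name, x$kind))
  if (x$kind == "continuous") {
    cat(sprintf("  AD:     %.4g +/- %.4g %s\n", x$class1$mean, x$class1$sd,
                x$units))
    cat(sprintf("  non-AD: %.4g +/- %.4g %s\n", x$class0$mean, x$class0$sd,
                x$units))
  } else if (x$kind == "binary") {
    cat(sprintf("  AD prevalence %.4f, non-AD prevalence %.4f\n",
                x$class1$prevalence, x$class0$prevalence))
  } else {
    cat("  AD prob:     ", paste(sprintf("%.4f", x$class1$prob),
                                 collapse = " "), "\n")
    cat("  non-AD prob: ", paste(sprintf("%.4f", x$class0$prob),
                                 collapse = " "), "\n")
  }
  invisible(x)
}

#' Convert feature specs to / from a flat data frame (CSV layout)
#'
#' One row per feature; categorical probability vectors and counts are packed
#' as `;`-separated strings so the table round-trips through CSV.
#'
#' @param specs list of [feature_spec()] objects.
#' @return `feature_specs_df()`: a data.frame; `df_to_feature_specs()`: a list
#'   of `feature_spec` objects.
#' @export
feature_specs_df <- function(specs) {
  pack <- function(v) if (is.null(v)) NA_character_ else
    paste(v, collapse = ";")
  rows <- lapply(specs, function(s) {
    g <- function(cls, key) s[[cls]][[key, exact = TRUE]] %||% NA_real_
    data.frame(
      feature_id = s$feature_id, name = s$name, long_name = s$long_name,
      kind = s$kind, units = s$units,
      mean1 = g("class1", "mean"), sd1 = g("class1", "sd"),
      mean0 = g("class0", "mean"), sd0 = g("class0", "sd"),
      prev1 = g("class1", "prevalence"), prev0 = g("class0", "prevalence"),
      count1 = g("class1", "count"), count0 = g("class0", "count"),
      n1 = g("class1", "n"), n0 = g("class0", "n"),
      prob1 = pack(s$class1$prob), prob0 = pack(s$class0$prob),
      counts1 = pack(s$class1$counts), counts0 = pack(s$class0$counts),
      values = pack(s$class1$values),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname feature_specs_df
#' @param df a data frame in the `feature_specs_df()` layout.
#' @export
df_to_feature_specs <- function(df) {
  unpack <- function(s) if (is.na(s)) NULL else
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    cls <- function(suf) {
      switch(r$kind,
        continuous = list(mean = r[[paste0("mean", suf)]],
                          sd = r[[paste0("sd", suf)]]),
        binary = list(prevalence = r[[paste0("prev", suf)]],
                      count = r[[paste0("count", suf)]],
                      n = r[[paste0("n", suf)]]),
        categorical = list(prob = unpack(r[[paste0("prob", suf)]]),
                           counts = unpack(r[[paste0("counts", suf)]]),
                           values = unpack(r$values)))
    }
    feature_spec(r$name, r$feature_id, r$kind, cls("1"), cls("0"),
                 units = r$units, long_name = r$long_name)
  })
}

#' Read / write feature-spec tables as CSV
#'
#' @param specs list of [feature_spec()] objects.
#' @param path file path.
#' @export
write_feature_specs <- function(specs, path) {
  utils::write.csv(feature_specs_df(specs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_specs
#' @export
read_feature_specs <- function(path) {
  df_to_feature_specs(utils::read.csv(path, stringsAsFactors = FALSE))
}
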