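#' Partition the majority class into balanced disjoint subsets
#'
#' Shuffles the majority-class indices with a fixed seed and cuts them into
#' `floor(length(N) / p_size)` pairwise-disjoint subsets of exactly `p_size`
#' elements each, the undersampling design of EasyEnsemble. Leftover indices
#' (fewer than `p_size`) are unused.
#'
#' @param n_indices integer vector of majority-class row indices.
#' @param p_size minority-class size (each subset gets this many rows).
#' @param seed integer seed driving the shuffle.
#' @return list of disjoint integer vectors, each of length `p_size`.
#' @export
partition_majority <- function(n_indices, p_size, seed = 1) {
  if (!is_count(p_size)) stopf("`p_size` must be a positive integer")
  if (length(n_indices) < p_size)
    stopf("insufficient majority class: %d indices for subsets of %d",
          length(n_indices), p_size)
  t_count <- floor(length(n_indices) / p_size)
  shuffled <- with_seed(seed, n_indices[sample.int(length(n_indices))])
  lapply(seq_len(t_count), function(i)
    shuffled[((i - 1L) * p_size + 1L):(i * p_size)])
}

#' EasyEnsemble and RS-EasyEnsemble classifiers
#'
#' `easy_ensemble()` fits the undersampling ensemble for severely imbalanced
#' two-class data: the majority class N is partitioned into disjoint subsets
#' the size of the minority class P, each subset joined with all of P forms a
#' balanced training set for one AdaBoost committee ([ada_boost()]), and the
#' fitted model predicts by vote over the committees.
#'
#' `rs_easy_ensemble()` is the random-subspace variant: `M` base committees
#' are trained, each on its balanced set restricted to a random subset of
#' `round(subspace_fraction * d)` features drawn per base; all `M` bases are
#' scored on a held-out validation split and only the best half are retained.
#' The ensemble prediction is the rounded mean vote of the selected half,
#' with half-up rounding so that an exact tie predicts the minority (AD)
#' class — the design favors recall. With `subspace_fraction = 1` and
#' `select = FALSE` the variant reduces exactly to `easy_ensemble()`.
#'
#' The best-half criterion is validation recall, tie-broken by validation
#' accuracy and then by base index; the validation split is stratified (by
#' the three-level stratum when available, otherwise by class).
#'
#' @param x feature matrix, or an `ad_cohort`/data.frame with `label` (and
#'   optionally `stratum`) columns, or a formula.
#' @param y 0/1 labels (1 = minority/AD); unused when `x` carries `label`.
#' @param t_count number of majority subsets / base committees for
#'   `easy_ensemble`; `"auto"` uses `floor(|N| / |P|)` capped at
#'   `max_subsets`.
#' @param max_subsets cap on the automatic subset count.
#' @param m number of base committees for `rs_easy_ensemble` (must be even).
#' @param subspace_fraction fraction of features given to each base
#'   (the study set 0.5).
#' @param rounds AdaBoost boosting rounds per base committee.
#' @param seed integer seed; (data, config, seed) fully determine the model.
#' @param selection_split fraction of the training data held out to score
#'   bases for best-half selection.
#' @param select logical; `FALSE` disables best-half selection (all bases
#'   vote and no validation split is made).
#' @param stratum optional stratum factor for the validation split.
#' @param data,formula standard modelling-interface arguments.
#' @param ... passed between methods.
#' @return object of class `easy_ensemble` or
#'   `c("rs_easy_ensemble", "easy_ensemble")` with `predict`, `print` and
#'   `summary` methods.
#' @examples
#' co <- generate_cohort(n_minority = 30, imbalance_ratio = 8, seed = 2)
#' fit <- easy_ensemble(co, seed = 2, rounds = 5)
#' table(predict(fit, co), co$label)
#' @export
easy_ensemble <- function(x, ...) UseMethod("easy_ensemble")

#' @rdname easy_ensemble
#' @export
easy_ensemble.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- as_label01(stats::model.response(mf))
  x <- as_feature_matrix(mf[-1L])
  easy_ensemble.default(x, y, ...)
}

#' @rdname easy_ensemble
#' @export
easy_ensemble.data.frame <- function(x, ...) {
  y <- as_label01(x$label)
  stratum <- x$stratum
  easy_ensemble.default(as_feature_matrix(x), y, stratum = stratum, ...)
}

#' @rdname easy_ensemble
#' @export
easy_ensemble.default <- function(x, y, t_count = "auto", rounds = 50,
                                  seed = 1, max_subsets = 50,
                                  stratum = NULL, ...) {
  x <- as_feature_matrix(x)
  y <- as_label01(y)
  p_size <- sum(y == 1L)
  n_size <- sum(y == 0L)
  if (p_size == 0L || n_size == 0L)
    stopf("invalid training data: both classes must be present")
  if (identical(t_count, "auto"))
    t_count <- min(max(floor(n_size / p_size), 1L), max_subsets)
  if (!is_count(t_count)) stopf("`t_count` must be a positive integer")
  fit <- ensemble_engine(x, y, m = t_count, subspace_fraction = 1,
                         rounds = rounds, seed = seed, select = FALSE,
                         selection_split = 0, stratum = stratum)
  class(fit) <- "easy_ensemble"
  fit$method <- "easyensemble"
  fit
}

#' @rdname easy_ensemble
#' @export
rs_easy_ensemble <- function(x, ...) UseMethod("rs_easy_ensemble")

#' @rdname easy_ensemble
#' @export
rs_easy_ensemble.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- as_label01(stats::model.response(mf))
  x <- as_feature_matrix(mf[-1L])
  rs_easy_ensemble.default(x, y, ...)
}

#' @rdname easy_ensemble
#' @export
rs_easy_ensemble.data.frame <- function(x, ...) {
  y <- as_label01(x$label)
  stratum <- x$stratum
  rs_easy_ensemble.default(as_feature_matrix(x), y, stratum = stratum, ...)
}

#' @rdname easy_ensemble
#' @export
rs_easy_ensemble.default <- function(x, y, m = 20, subspace_fraction = 0.5,
                                     rounds = 50, seed = 1,
                                     selection_split = 0.25, select = TRUE,
                                     stratum = NULL, ...) {
  x <- as_feature_matrix(x)
  y <- as_label01(y)
  if (!is_count(m, min = 2)) stopf("`m` must be an integer >= 2")
  if (select && m %% 2 != 0)
    stopf("`m` must be even so that exactly half the bases can be selected")
  if (!is.numeric(subspace_fraction) || subspace_fraction <= 0 ||
      subspace_fraction > 1)
    stopf("`subspace_fraction` must lie in (0, 1]")
  if (round(subspace_fraction * ncol(x)) < 1)
    stopf("empty subspace: fraction %g of %d features rounds to zero",
          subspace_fraction, ncol(x))
  fit <- ensemble_engine(x, y, m = m, subspace_fraction = subspace_fraction,
                         rounds = rounds, seed = seed, select = select,
                         selection_split = selection_split,
                         stratum = stratum)
  class(fit) <- c("rs_easy_ensemble", "easy_ensemble")
  fit$method <- "rs_easyensemble"
  fit
}

## shared trainer: EasyEnsemble is the fraction = 1 / select = FALSE case,
## and consumes the RNG identically so the two coincide seed-for-seed
ensemble_engine <- function(x, y, m, subspace_fraction, rounds, seed,
                            select, selection_split, stratum) {
  d <- ncol(x)
  with_seed(seed, {
    if (select) {
      strat <- if (!is.null(stratum)) factor(stratum) else factor(y)
      idx <- split_indices(strat, 1 - selection_split)
      tr <- idx$first; va <- idx$second
    } else {
      tr <- seq_along(y); va <- integer(0)
    }
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    p_idx <- which(ytr == 1L)
    n_idx <- which(ytr == 0L)
    if (!length(p_idx) || !length(n_idx))
      stopf("invalid training data: both classes must be present")
    if (length(n_idx) < length(p_idx))
      stopf("insufficient majority class for balanced undersampling")
    parts <- partition_subsets(n_idx, length(p_idx))
    t_avail <- length(parts)

    bases <- vector("list", m)
    for (i in seq_len(m)) {
      subspace <- if (subspace_fraction < 1)
        sort(sample.int(d, round(subspace_fraction * d)))
      else seq_len(d)
      t_id <- ((i - 1L) %% t_avail) + 1L
      rows <- c(p_idx, parts[[t_id]])
      clf <- ada_boost(xtr[rows, subspace, drop = FALSE], ytr[rows],
                       rounds = rounds)
      bases[[i]] <- list(classifier = clf, subspace = subspace,
                         majority_subset_id = t_id,
                         n_pos = length(p_idx), n_neg = length(parts[[t_id]]),
                         validation_score = NA_real_, selected = TRUE)
    }

    if (select) {
      xva <- x[va, , drop = FALSE]; yva <- y[va]
      scores <- t(vapply(bases, function(b) {
        pred <- predict(b$classifier, xva[, b$subspace, drop = FALSE])
        pos <- yva == 1L
        rec <- if (any(pos)) mean(pred[pos] == 1L) else 0
        acc <- mean(pred == yva)
        c(rec, acc)
      }, numeric(2)))
      ord <- order(-scores[, 1], -scores[, 2], seq_len(m))
      keep <- ord[seq_len(m %/% 2L)]
      for (i in seq_len(m)) {
        bases[[i]]$validation_score <- scores[i, 1]
        bases[[i]]$selected <- i %in% keep
      }
    }

    structure(list(bases = bases, m = m,
                   subspace_fraction = subspace_fraction,
                   rounds = rounds, seed = as.integer(seed),
                   select = select, d = d,
                   p_size = length(p_idx), n_size = length(n_idx),
                   t_count = t_avail),
              class = "easy_ensemble")
  })
}

## disjoint equal chunks of already-shuffled-in-place indices; the shuffle
## happens here so partition_majority and the engine share one code path
partition_subsets <- function(n_idx, p_size) {
  t_count <- floor(length(n_idx) / p_size)
  shuffled <- n_idx[sample.int(length(n_idx))]
  lapply(seq_len(t_count), function(i)
    shuffled[((i - 1L) * p_size + 1L):(i * p_size)])
}

## two-way stratified row split at proportion `prop`
split_indices <- function(strat, prop) {
  first <- unlist(lapply(split(seq_along(strat), strat), function(ii) {
    if (!length(ii)) return(integer(0))
    k <- min(max(1L, round(length(ii) * prop)), length(ii))
    ii[sample.int(length(ii), k)]
  }), use.names = FALSE)
  first <- sort(first)
  list(first = first, second = setdiff(seq_along(strat), first))
}

#' Predict method for undersampling ensembles
#'
#' Each selected base committee votes 0/1 on its own feature subspace; the
#' ensemble label is the mean vote rounded half-up, so a selected-half vote
#' sum `s` out of `M/2` bases gives `Round(2 s / M)` and an exact 0.5 tie
#' predicts class 1 (AD).
#'
#' @param object an [easy_ensemble()] / [rs_easy_ensemble()] fit.
#' @param newdata feature matrix or cohort with the training feature count.
#' @param type `"class"` for 0/1 labels, `"vote"` for the mean selected vote.
#' @param ... unused.
#' @export
predict.easy_ensemble <- function(object, newdata,
                                  type = c("class", "vote"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$d)
    stopf("newdata has %d columns; model was trained on %d", ncol(x),
          object$d)
  sel <- Filter(function(b) b$selected, object$bases)
  votes <- rep(0, nrow(x))
  for (b in sel)
    votes <- votes + predict(b$classifier, x[, b$subspace, drop = FALSE])
  mean_vote <- votes / length(sel)
  if (type == "vote") mean_vote else as.integer(mean_vote >= 0.5)
}

#' @export
print.easy_ensemble <- function(x, ...) {
  nm <- if (inherits(x, "rs_easy_ensemble")) "RS-EasyEnsemble"
        else "EasyEnsemble"
  cat(sprintf("<%s: %d base committees (%d selected), %d boosting rounds>\n",
              nm, x$m, sum(vapply(x$bases, `[[`, TRUE, "selected")),
              x$rounds))
  cat(sprintf("  balanced sets: %d per class; majority subsets available: %d; subspace fraction %.2f\n",
              x$p_size, x$t_count, x$subspace_fraction))
  invisible(x)
}

#' @export
summary.easy_ensemble <- function(object, ...) {
  sel <- vapply(object$bases, `[[`, TRUE, "selected")
  sc <- vapply(object$bases, `[[`, NA_real_, "validation_score")
  df <- data.frame(
    base = seq_len(object$m),
    majority_subset = vapply(object$bases, `[[`, 1L, "majority_subset_id"),
    subspace_size = vapply(object$bases, function(b) length(b$subspace), 1L),
    validation_recall = sc,
    selected = sel)
  structure(list(model = object, bases = df),
            class = "summary.easy_ensemble")
}

#' @export
print.summary.easy_ensemble <- function(x, ...) {
  print(x$model)
  print(x$bases, row.names = FALSE)
  invisible(x)
}
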