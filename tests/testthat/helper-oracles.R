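## Independent oracles and fixture builders used across the suite.

## Naive discrete AdaBoost with stumps, written as a direct transcription of
## the algorithm: brute-force double loop over candidate thresholds and
## orientations each round. Deliberately slow and independent of the
## package's vectorized implementation.
naive_adaboost <- function(x, y01, rounds) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(rounds)) {
    best <- NULL
    for (j in seq_len(ncol(x))) {
      xs <- sort(unique(x[, j]))
      cand <- c(-Inf, (xs[-length(xs)] + xs[-1]) / 2, Inf)
      for (thr in cand) {
        for (dir in c(1, -1)) {
          h <- dir * ifelse(x[, j] > thr, 1, -1)
          err <- sum(w[h != y])
          if (is.null(best) || err < best$err - 1e-15)
            best <- list(err = err, feature = j, threshold = thr, dir = dir)
        }
      }
    }
    h <- best$dir * ifelse(x[, best$feature] > best$threshold, 1, -1)
    eps <- min(max(best$err, 1e-12), 1 - 1e-12)
    alpha <- 0.5 * log((1 - eps) / eps)
    stumps[[t]] <- best
    alphas <- c(alphas, alpha)
    if (eps <= 1e-12) break
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas,
       predict = function(newx) {
         s <- rep(0, nrow(newx))
         for (i in seq_along(stumps)) {
           st <- stumps[[i]]
           s <- s + alphas[i] * st$dir *
             ifelse(newx[, st$feature] > st$threshold, 1, -1)
         }
         as.integer(s >= 0)
       })
}

## permutation p-value for independence in an r x 2 count table, by
## shuffling group membership of the underlying observations
permutation_chi2_p <- function(counts, n_perm = 10000, seed = 42) {
  obs_stat <- pearson_chi2(counts)$statistic
  levels_r <- rep(seq_len(nrow(counts)), rowSums(counts))
  group <- rep(seq_len(ncol(counts)), colSums(counts))
  withr::with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      g <- sample(group)
      tab <- table(factor(levels_r, seq_len(nrow(counts))),
                   factor(g, seq_len(ncol(counts))))
      st <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$statistic)
      if (st >= obs_stat - 1e-12) hits <- hits + 1L
    }
    hits / n_perm
  })
}

## small synthetic cohort with `n_sep` class-separated Gaussian features
## (gap in SD units) and `n_null` null features
separated_specs <- function(n_sep, n_null, gap = 1) {
  specs <- list()
  for (i in seq_len(n_sep))
    specs[[length(specs) + 1L]] <-
      feature_spec(paste0("sep", i), i, "continuous",
                   class1 = list(mean = gap, sd = 1),
                   class0 = list(mean = 0, sd = 1))
  for (i in seq_len(n_null))
    specs[[length(specs) + 1L]] <-
      feature_spec(paste0("null", i), n_sep + i, "continuous",
                   class1 = list(mean = 0, sd = 1),
                   class0 = list(mean = 0, sd = 1))
  specs[[length(specs) + 1L]] <-
    feature_spec("thoracalgia", n_sep + n_null + 1L, "binary",
                 class1 = list(prevalence = 0.3),
                 class0 = list(prevalence = 0.2))
  specs
}

make_separable_cohort <- function(n1 = 40, n0 = 200, gap = 10, seed = 5) {
  generate_cohort(separated_specs(3, 1, gap = gap), n_minority = n1,
                  imbalance_ratio = n0 / n1, seed = seed)
}

## a constant-vote classifier for constructing ensembles with forced votes
const_clf <- function(vote) structure(list(vote = vote), class = "const_clf")
predict.const_clf <- function(object, newdata, ...)
  rep(as.integer(object$vote), nrow(newdata))
registerS3method("predict", "const_clf", predict.const_clf)

## hand-assemble an ensemble whose selected bases cast fixed votes
forced_vote_ensemble <- function(votes_selected, m, d = 3) {
  bases <- lapply(votes_selected, function(v)
    list(classifier = const_clf(v), subspace = seq_len(d),
         majority_subset_id = 1L, n_pos = 1L, n_neg = 1L,
         validation_score = NA_real_, selected = TRUE))
  structure(list(bases = bases, m = m, subspace_fraction = 1,
                 rounds = 1, seed = 0L, select = TRUE, d = d,
                 p_size = 1L, n_size = 1L, t_count = 1L),
            class = "easy_ensemble")
}
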