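test_that("majority partition yields disjoint balanced subsets", {
  parts <- partition_majority(1:650, 10, seed = 1)
  expect_length(parts, 65)
  expect_true(all(lengths(parts) == 10))
  expect_equal(length(unique(unlist(parts))), 650)

  parts <- partition_majority(1:657, 10, seed = 2)
  expect_length(parts, 65)
  expect_equal(length(unlist(parts)), 650)  # 7 leftover indices unused

  expect_error(partition_majority(1:5, 10), "insufficient")
})

test_that("partition is disjoint and exact over random designs", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      p_size <- sample(1:40, 1)
      n_size <- p_size * sample(1:8, 1) + sample(0:(p_size - 1), 1)
      parts <- partition_majority(seq_len(n_size), p_size,
                                  seed = sample(1e6, 1))
      expect_true(all(lengths(parts) == p_size))
      all_idx <- unlist(parts)
      expect_equal(anyDuplicated(all_idx), 0)
      expect_length(parts, floor(n_size / p_size))
    }
  })
})

test_that("every base committee trains on an exactly balanced set", {
  co <- make_separable_cohort(n1 = 25, n0 = 150, gap = 2, seed = 6)
  ee <- easy_ensemble(co, rounds = 3, seed = 1)
  expect_equal(ee$t_count, 6)
  for (b in ee$bases) expect_equal(b$n_pos, b$n_neg)
  rs <- rs_easy_ensemble(co, m = 6, rounds = 3, seed = 1)
  for (b in rs$bases) {
    expect_equal(b$n_pos, b$n_neg)
    expect_equal(b$n_pos, rs$p_size)
  }
})

test_that("subspaces have the configured size and exactly half the bases are kept", {
  co <- generate_cohort(n_minority = 30, imbalance_ratio = 6, seed = 12)
  d <- ncol(cohort_features(co))
  rs <- rs_easy_ensemble(co, m = 10, subspace_fraction = 0.5, rounds = 3,
                         seed = 5)
  sizes <- vapply(rs$bases, function(b) length(b$subspace), 1L)
  expect_true(all(sizes == round(0.5 * d)))
  for (b in rs$bases) expect_equal(anyDuplicated(b$subspace), 0)
  expect_equal(sum(vapply(rs$bases, `[[`, TRUE, "selected")), 5)
  # selection keeps the top validation recalls
  sc <- vapply(rs$bases, `[[`, 1, "validation_score")
  sel <- vapply(rs$bases, `[[`, TRUE, "selected")
  expect_gte(min(sc[sel]), max(sc[!sel]))
})

test_that("the rounded-average vote follows the published formula", {
  x <- matrix(0, 4, 3)
  # M = 10, five selected bases, vote sum 3 -> (2/10) * 3 = 0.6 -> 1
  m10 <- forced_vote_ensemble(c(1, 1, 1, 0, 0), m = 10)
  expect_equal(predict(m10, x), rep(1L, 4))
  expect_equal(predict(m10, x, type = "vote"), rep(0.6, 4))
  # vote sum 2 -> 0.4 -> 0
  expect_equal(predict(forced_vote_ensemble(c(1, 1, 0, 0, 0), m = 10), x),
               rep(0L, 4))
  # M = 8, vote sum 2 -> exactly 0.5 -> rounds half-up to the AD class
  expect_equal(predict(forced_vote_ensemble(c(1, 1, 0, 0), m = 8), x),
               rep(1L, 4))
})

test_that("adding a positive vote never flips a positive prediction off", {
  x <- matrix(0, 1, 3)
  for (k in 0:4) {
    votes <- c(rep(1, k), rep(0, 4 - k))
    p1 <- predict(forced_vote_ensemble(votes, m = 8), x)
    votes2 <- c(rep(1, min(k + 1, 4)), rep(0, max(3 - k, 0)))
    p2 <- predict(forced_vote_ensemble(votes2, m = 8), x)
    expect_gte(p2, p1)
  }
})

test_that("full-subspace unselected RS reduces exactly to EasyEnsemble", {
  co <- make_separable_cohort(n1 = 20, n0 = 130, gap = 1.5, seed = 8)
  ee <- easy_ensemble(co, rounds = 4, seed = 17)
  rs <- rs_easy_ensemble(co, m = ee$t_count, subspace_fraction = 1,
                         select = FALSE, rounds = 4, seed = 17)
  expect_identical(predict(ee, co), predict(rs, co))
  expect_identical(predict(ee, co, type = "vote"),
                   predict(rs, co, type = "vote"))
})

test_that("ensembles are seed-deterministic and validate arguments", {
  co <- make_separable_cohort(n1 = 20, n0 = 100, gap = 2, seed = 9)
  f1 <- rs_easy_ensemble(co, m = 4, rounds = 3, seed = 2)
  f2 <- rs_easy_ensemble(co, m = 4, rounds = 3, seed = 2)
  expect_identical(predict(f1, co), predict(f2, co))
  f3 <- rs_easy_ensemble(co, m = 4, rounds = 3, seed = 3)
  expect_false(identical(f1$bases, f3$bases))
  expect_error(rs_easy_ensemble(co, m = 5, rounds = 3), "even")
  expect_error(rs_easy_ensemble(co, m = 4, subspace_fraction = 0), "fraction")
  xs <- cohort_features(co)
  expect_error(easy_ensemble(xs, rep(1L, nrow(xs))), "both classes")
  expect_error(predict(f1, xs[, 1:2]), "columns")
})

test_that("ensembles achieve full training recall on separable data", {
  co <- make_separable_cohort(n1 = 30, n0 = 200, gap = 10, seed = 10)
  ee <- easy_ensemble(co, rounds = 10, seed = 1)
  pred <- predict(ee, co)
  expect_equal(pred[co$label == 1L], rep(1L, 30))
})

test_that("the formula interface matches the matrix interface", {
  co <- make_separable_cohort(n1 = 15, n0 = 90, gap = 3, seed = 13)
  f1 <- easy_ensemble(label ~ sep1 + sep2 + sep3 + null1 + thoracalgia,
                      data = co, rounds = 3, seed = 4)
  f2 <- easy_ensemble(cohort_features(co), co$label, rounds = 3, seed = 4)
  expect_equal(predict(f1, cohort_features(co)), predict(f2, co))
})
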