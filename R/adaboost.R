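#' Discrete AdaBoost with decision stumps
#'
#' Classic discrete AdaBoost (AdaBoost.M1 with two classes) using depth-1
#' axis-aligned decision stumps as weak learners, the base classifier used
#' inside the undersampling ensembles. Each round fits the stump minimizing
#' the weighted 0/1 error by exhaustive threshold search over every feature
#' (both orientations), then reweights samples multiplicatively. Training is
#' fully deterministic: ties between equally good stumps break towards the
#' lowest feature index, then the lowest threshold, then the `x > t -> 1`
#' orientation.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y labels coded 0/1 (1 = positive / minority class).
#' @param rounds number of boosting rounds (weak learners).
#' @return object of class `ada_boost` with a [predict.ada_boost()] method.
#' @examples
#' x <- matrix(c(rnorm(30), rnorm(30, 3)), ncol = 2, byrow = TRUE)
#' fit <- ada_boost(x, rep(c(1, 0), each = 15), rounds = 10)
#' predict(fit, x)
#' @export
ada_boost <- function(x, y, rounds = 50, ...) {
  x <- as_feature_matrix(x)
  y <- as_label01(y)
  if (nrow(x) != length(y)) stopf("x and y sizes differ")
  if (length(unique(y)) < 2)
    stopf("invalid training data: both classes must be present")
  if (!is_count(rounds)) stopf("`rounds` must be a positive integer")
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(x); d <- ncol(x)

  ## per-column presorted views, computed once
  ords <- lapply(seq_len(d), function(j) order(x[, j]))
  xsorted <- lapply(seq_len(d), function(j) x[ords[[j]], j])
  ## split k allowed only between distinct sorted values (k = 0..n)
  allowed <- lapply(xsorted, function(xs)
    c(TRUE, xs[-length(xs)] < xs[-1], TRUE))

  w <- rep(1 / n, n)
  stumps <- vector("list", rounds)
  alphas <- numeric(rounds)
  used <- 0L
  for (t in seq_len(rounds)) {
    st <- fit_stump(x, ys, w, ords, xsorted, allowed)
    h <- stump_predict(st, x)
    eps <- sum(w[h != ys])
    eps <- min(max(eps, 1e-12), 1 - 1e-12)
    alpha <- 0.5 * log((1 - eps) / eps)
    used <- used + 1L
    stumps[[used]] <- st
    alphas[used] <- alpha
    if (eps <= 1e-12) break  # perfect weak learner: committee is decided
    w <- w * exp(-alpha * ys * h)
    w <- w / sum(w)
  }
  structure(list(stumps = stumps[seq_len(used)],
                 alphas = alphas[seq_len(used)],
                 rounds = rounds, d = d),
            class = "ada_boost")
}

## minimize weighted error over feature j, threshold t, orientation s:
##   h(x) = s * sign(x_j > t)  (coded -1 / +1)
fit_stump <- function(x, ys, w, ords, xsorted, allowed) {
  n <- length(ys)
  best <- list(err = Inf)
  wp_tot <- sum(w[ys > 0])
  wn_tot <- sum(w[ys < 0])
  for (j in seq_along(ords)) {
    ord <- ords[[j]]
    wo <- w[ord]; yo <- ys[ord]
    cwp <- c(0, cumsum(wo * (yo > 0)))   # positive weight in left block
    cwn <- c(0, cumsum(wo * (yo < 0)))
    ## orientation +1: left block -> -1, right block -> +1
    err_pos <- cwp + (wn_tot - cwn)
    err_neg <- cwn + (wp_tot - cwp)
    ok <- allowed[[j]]
    e1 <- err_pos; e1[!ok] <- Inf
    e2 <- err_neg; e2[!ok] <- Inf
    k1 <- which.min(e1); k2 <- which.min(e2)
    if (e1[k1] < best$err - 1e-15) {
      best <- list(err = e1[k1], feature = j, k = k1 - 1L, dir = 1)
    }
    if (e2[k2] < best$err - 1e-15) {
      best <- list(err = e2[k2], feature = j, k = k2 - 1L, dir = -1)
    }
  }
  xs <- xsorted[[best$feature]]
  thr <- if (best$k == 0L) -Inf
         else if (best$k == n) Inf
         else (xs[best$k] + xs[best$k + 1L]) / 2
  list(feature = best$feature, threshold = thr, dir = best$dir)
}

stump_predict <- function(st, x) {
  h <- ifelse(x[, st$feature] > st$threshold, 1, -1)
  st$dir * h
}

#' Predict method for AdaBoost committees
#'
#' @param object an [ada_boost()] fit.
#' @param newdata feature matrix with the training dimension.
#' @param type `"class"` for 0/1 labels (zero margin counts as positive) or
#'   `"score"` for the signed committee margin.
#' @param ... unused.
#' @export
predict.ada_boost <- function(object, newdata,
                              type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$d)
    stopf("newdata has %d columns; model was trained on %d", ncol(x),
          object$d)
  score <- rep(0, nrow(x))
  for (i in seq_along(object$stumps))
    score <- score + object$alphas[i] * stump_predict(object$stumps[[i]], x)
  if (type == "score") score else as.integer(score >= 0)
}

#' @export
print.ada_boost <- function(x, ...) {
  cat(sprintf("<ada_boost: %d stump rounds over %d features>\n",
              length(x$stumps), x$d))
  invisible(x)
}
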