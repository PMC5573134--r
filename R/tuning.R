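# K-fold cross-validation for the penalty level.

#' Balanced K-fold assignment
#'
#' Random permutation followed by contiguous blocks; every fold has between
#' `floor(n/K)` and `ceiling(n/K)` members. Deterministic given `seed`.
#'
#' @param n Number of observations. @param K Number of folds (2 <= K <= n).
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..K), length n.
#' @export
#' @examples
#' table(kfold_split(10, 3, seed = 1))  # sizes 4, 3, 3
kfold_split <- function(n, K, seed = 1L) {
  n <- as.integer(n); K <- as.integer(K)
  if (K < 2L || K > n) stop("need 2 <= K <= n")
  sizes <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep.int(seq_len(K), sizes)
  fold
}

#' Cross-validate a penalty path
#'
#' Warm-started path fits within each training fold; the CV score per
#' penalty level is the mean over folds of the weighted held-out mean
#' squared prediction error (held-out observations keep their own weights,
#' so outliers do not dominate the selection). The reported standard error
#' is `sd(fold means)/sqrt(K)`. The selected penalty attains the minimum
#' mean CV error; on ties the largest such penalty wins (the path is
#' descending and the first index is taken).
#'
#' @param X,y Data. @param w Observation weights in \[0, 1\].
#' @param v Positive penalty weights.
#' @param lambda_path Descending vector of penalty levels.
#' @param K Number of folds. @param seed Seed for the fold assignment
#'   (ignored when `foldid` is given).
#' @param foldid Optional precomputed fold labels.
#' @param mix Elastic-net mixing. @param tol,max_iter Solver controls.
#' @return Object of class `"ral_cv"`: `lambda_path`, `mean_cv_error`,
#'   `se_cv_error`, `fold_assignments`, `lambda_selected`, `fold_means`.
#' @export
cross_validate <- function(X, y, w, v, lambda_path, K = 10L, seed = 1L,
                           foldid = NULL, mix = 1, tol = 1e-7,
                           max_iter = 10000L) {
  d <- .validate_data(X, y)
  if (is.unsorted(rev(lambda_path), strictly = FALSE)) {
    stop("lambda_path must be descending")
  }
  fold <- foldid %||% kfold_split(d$n, K, seed)
  K <- max(fold)
  # each training set (complement of a fold) needs >= 2 observations;
  # held-out folds of size 1 (leave-one-out) are fine
  if (any(d$n - tabulate(fold, K) < 2L)) {
    stop("every training fold needs at least 2 observations")
  }
  nlam <- length(lambda_path)
  fold_means <- matrix(NA_real_, K, nlam)
  for (k in seq_len(K)) {
    ho <- fold == k
    fit <- .wal_core(d$X[!ho, , drop = FALSE], d$y[!ho], w[!ho], v,
                     lambda_path, mix, tol, max_iter)
    pred <- d$X[ho, , drop = FALSE] %*% fit$beta +
      rep(fit$intercept, each = sum(ho))
    sqerr <- (d$y[ho] - pred)^2
    swh <- sum(w[ho])
    fold_means[k, ] <- if (swh > 1e-10) {
      colSums(sqerr * w[ho]) / swh
    } else {
      colMeans(sqerr)
    }
  }
  mean_cv <- colMeans(fold_means)
  se_cv <- apply(fold_means, 2L, sd) / sqrt(K)
  sel <- which.min(mean_cv)  # first index = largest lambda on ties
  structure(list(lambda_path = lambda_path, mean_cv_error = mean_cv,
                 se_cv_error = se_cv, fold_assignments = fold,
                 lambda_selected = lambda_path[sel], fold_means = fold_means),
            class = "ral_cv")
}

#' @export
print.ral_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d lambda values: selected lambda = %.5g (CV error %.4g)\n",
              max(x$fold_assignments), length(x$lambda_path),
              x$lambda_selected, min(x$mean_cv_error)))
  invisible(x)
}
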