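# Initial estimators and the weighted adaptive-lasso solver.
#
# The robust fit minimises
#   (1/2n) sum_i w_i (y_i - b0 - x_i' beta)^2
#     + lambda * sum_j v_j (mix |gamma_j| + (1-mix)/2 gamma_j^2)
# where gamma_j = s_j beta_j is the coefficient of the j-th predictor after
# standardization to weighted mean 0 / variance 1 (the usual convention of
# penalised-regression software: the penalty is scale-equivariant in the
# predictors). Observation weights w come from the Pearson-residual scheme;
# adaptive penalty weights are v_j = 1 / max(|beta_init_j|, 1e-8). The
# intercept is never penalised; coefficients are reported on the original
# scale.

.penalty_floor <- 1e-8

.validate_data <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (length(y) < 2L) stop("need at least two observations")
  if (ncol(X) < 1L) stop("X must have at least one column")
  if (any(!is.finite(X))) stop("X contains non-finite entries")
  if (any(!is.finite(y))) stop("y contains non-finite entries")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  list(X = X, y = y, n = nrow(X), p = ncol(X))
}

# Weighted standardization used by the solver: columns to weighted mean 0 and
# weighted variance 1, response weighted-centered. Zero-variance columns are
# dropped (coefficient 0).
.wstd <- function(X, y, w) {
  sw <- sum(w)
  xbar <- colSums(X * w) / sw
  Z <- sweep(X, 2L, xbar)
  s <- sqrt(colSums(Z^2 * w) / sw)
  keep <- which(s > 1e-10)
  Z <- sweep(Z[, keep, drop = FALSE], 2L, s[keep], "/")
  ybar <- sum(w * y) / sw
  list(Z = Z, ytil = y - ybar, xbar = xbar, s = s, ybar = ybar, keep = keep)
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - t, 0)`, the exact univariate lasso update.
#'
#' @param z Numeric vector.
#' @param t Nonnegative threshold.
#' @return Numeric vector.
#' @export
#' @examples
#' soft_threshold(3, 1)     # 2
#' soft_threshold(-0.5, 1)  # 0
soft_threshold <- function(z, t) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  sign(z) * pmax(abs(z) - t, 0)
}

#' Ridge initial estimator
#'
#' L2-penalised least squares with unpenalised intercept, solved through the
#' SVD of the standardized design; used to seed the adaptive penalty when
#' p >> n. The ridge penalty is either a fixed nonnegative number or `"cv"`
#' (10-fold cross-validation over a log-spaced grid). The residual scale
#' `sigma` is the robust MAD estimate `1.4826 * median(|r - median(r)|)`.
#'
#' @param X Design matrix (n x p). @param y Response vector.
#' @param ridge_penalty Nonnegative number, or `"cv"`.
#' @param nfolds CV folds when `ridge_penalty = "cv"`.
#' @param seed Seed for the CV fold assignment.
#' @return Object of class `"ral_initial"` with `beta`, `intercept`,
#'   `sigma`, `method`, `ridge_penalty`.
#' @export
fit_ridge_initial <- function(X, y, ridge_penalty = "cv", nfolds = 10L,
                              seed = 1L) {
  d <- .validate_data(X, y)
  if (d$n < 3L) stop("need at least three observations")
  xbar <- colMeans(d$X)
  Z <- sweep(d$X, 2L, xbar)
  s <- sqrt(colMeans(Z^2))
  drop0 <- s <= 1e-10
  if (any(drop0)) {
    warning(sum(drop0), " zero-variance column(s); coefficients set to 0")
  }
  keep <- which(!drop0)
  Z <- sweep(Z[, keep, drop = FALSE], 2L, s[keep], "/")
  ybar <- mean(d$y)
  ytil <- d$y - ybar

  ridge_gamma <- function(Ztr, ytr, lam) {
    sv <- svd(Ztr)
    shrink <- sv$d / (sv$d^2 + nrow(Ztr) * lam)
    sv$v %*% (shrink * crossprod(sv$u, ytr))
  }

  if (identical(ridge_penalty, "cv")) {
    grid <- 10^seq(-4, 3, length.out = 50L)
    K <- min(nfolds, d$n)
    fold <- kfold_split(d$n, K, seed)
    errs <- matrix(NA_real_, K, length(grid))
    for (k in seq_len(K)) {
      ho <- fold == k
      sv <- svd(Z[!ho, , drop = FALSE])
      uty <- crossprod(sv$u, ytil[!ho])
      for (g in seq_along(grid)) {
        gam <- sv$v %*% ((sv$d / (sv$d^2 + sum(!ho) * grid[g])) * uty)
        pred <- Z[ho, , drop = FALSE] %*% gam
        errs[k, g] <- mean((ytil[ho] - pred)^2)
      }
    }
    lam <- grid[which.min(colMeans(errs))]
  } else {
    stopifnot(is.numeric(ridge_penalty), ridge_penalty >= 0)
    lam <- ridge_penalty
  }

  gam <- if (lam == 0 && d$n > length(keep)) {
    qr.coef(qr(Z), ytil)
  } else {
    ridge_gamma(Z, ytil, lam)
  }
  beta <- numeric(d$p)
  beta[keep] <- gam / s[keep]
  names(beta) <- colnames(d$X)
  intercept <- ybar - sum(beta * xbar)
  r <- d$y - intercept - drop(d$X %*% beta)
  sigma <- 1.4826 * median(abs(r - median(r)))
  if (sigma <= 1e-10) sigma <- max(sd(r), 1e-8)
  structure(list(beta = beta, intercept = intercept, sigma = sigma,
                 method = "ridge", ridge_penalty = lam),
            class = "ral_initial")
}

# Least-trimmed-squares style warm start for the bisquare IRLS: the best of
# the LS fit, an IRLS LAD fit, and `nsamp` elemental-subset fits refined by
# concentration steps, judged by the trimmed sum of squared residuals with
# coverage h = (n + q + 1) / 2. Subsampling uses a fixed internal seed so
# the estimator is deterministic in the data.
.lts_start <- function(A, y, wls, nsamp = 200L) {
  n <- nrow(A)
  q <- ncol(A)
  h <- (n + q + 1L) %/% 2L
  crit <- function(b) sum(sort((y - drop(A %*% b))^2)[seq_len(h)])
  cstep <- function(b, k) {
    for (i in seq_len(k)) {
      idx <- order((y - drop(A %*% b))^2)[seq_len(h)]
      b2 <- tryCatch(qr.coef(qr(A[idx, , drop = FALSE]), y[idx]),
                     error = function(e) NULL)
      if (is.null(b2) || any(is.na(b2))) return(b)
      b <- b2
    }
    b
  }
  ls_fit <- qr.coef(qr(A), y)
  # IRLS LAD (median regression) candidate
  b <- ls_fit
  for (it in seq_len(50L)) {
    r <- y - drop(A %*% b)
    b_new <- wls(1 / pmax(abs(r), 1e-6))
    if (any(is.na(b_new))) { b_new <- b; break }
    if (max(abs(b_new - b)) < 1e-8 * max(1, max(abs(b)))) { b <- b_new; break }
    b <- b_new
  }
  cands <- list(ls_fit, b)
  elems <- with_seed(1742L, {
    lapply(seq_len(nsamp), function(s) sample.int(n, q + 1L))
  })
  for (idx in elems) {
    be <- tryCatch(qr.coef(qr(A[idx, , drop = FALSE]), y[idx]),
                   error = function(e) NULL)
    if (!is.null(be) && !any(is.na(be))) cands[[length(cands) + 1L]] <- be
  }
  scores <- vapply(cands, crit, 0)
  best <- cands[[1L]]
  best_score <- Inf
  for (i in order(scores)[seq_len(min(10L, length(cands)))]) {
    bc <- cstep(cands[[i]], 3L)
    sc <- crit(bc)
    if (sc < best_score) {
      best_score <- sc
      best <- bc
    }
  }
  best
}

#' Tukey bisquare M-estimator
#'
#' Iteratively reweighted least squares for the bisquare psi, warm-started
#' by a least-trimmed-squares subsample search (elemental subsets plus
#' concentration steps, competing against the LS and LAD fits) and run with
#' the residual scale frozen at the warm start's MAD, as in MM-estimation.
#' Requires n > p; for wide designs use [fit_ridge_initial()].
#'
#' @param X Design matrix. @param y Response.
#' @param c Bisquare tuning constant (4.685 gives 95% normal efficiency).
#' @param max_iter,tol IRLS controls; convergence when the largest
#'   coefficient change drops below `tol * max(1, max|beta|)`.
#' @return Object of class `"ral_initial"` with `beta`, `intercept`,
#'   `sigma`, `converged` and the final IRLS observation weights
#'   (`irls_weights`).
#' @export
fit_tukey_m <- function(X, y, c = 4.685, max_iter = 100L, tol = 1e-8) {
  d <- .validate_data(X, y)
  if (d$n <= d$p) {
    stop("n <= p: Tukey M-estimation needs n > p; use fit_ridge_initial()")
  }
  A <- cbind(`(Intercept)` = 1, d$X)
  wls <- function(wt) {
    sw <- sqrt(wt)
    qr.coef(qr(A * sw), y * sw)
  }
  mad_scale <- function(r) 1.4826 * median(abs(r - median(r)))

  # High-breakdown warm start in the least-trimmed-squares style: elemental
  # subsets refined by concentration steps, competing against the LS and
  # LAD fits on the trimmed sum of squares. A redescending bisquare started
  # from plain least squares is dragged away by clusters of gross outliers.
  b <- .lts_start(A, d$y, wls)

  # Bisquare M-step with the scale frozen at the warm-up MAD (preliminary
  # scale, as in MM-estimation); re-estimating scale each sweep degrades
  # the fit under heavy asymmetric contamination.
  s <- mad_scale(d$y - drop(A %*% b))
  converged <- FALSE
  wt <- rep(1, d$n)
  for (it in seq_len(max_iter)) {
    r <- d$y - drop(A %*% b)
    if (s <= 1e-12 * (mad(d$y) + 1)) { converged <- TRUE; break }  # exact fit
    u <- r / (c * s)
    wt <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(wt > 0) <= d$p) {
      warning("bisquare IRLS degenerated (too few positive weights); ",
              "returning last iterate")
      break
    }
    b_new <- wls(wt)
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol * max(1, max(abs(b)))) { converged <- TRUE; break }
  }
  if (!converged && s > 1e-12 * (mad(d$y) + 1)) {
    warning("Tukey IRLS did not converge in ", max_iter, " iterations")
  }
  r <- d$y - drop(A %*% b)
  sigma <- mad_scale(r)
  if (sigma <= 1e-10) sigma <- max(sd(r), 1e-8)
  beta <- b[-1L]
  names(beta) <- colnames(d$X)
  structure(list(beta = beta, intercept = unname(b[1L]), sigma = sigma,
                 method = "tukey_m", converged = converged,
                 irls_weights = wt),
            class = "ral_initial")
}

#' @export
print.ral_initial <- function(x, ...) {
  cat(sprintf("Initial estimate (%s): p = %d, sigma = %.4g\n",
              x$method, length(x$beta), x$sigma))
  invisible(x)
}

#' Adaptive penalty weights from an initial estimate
#'
#' `v_j = 1 / max(|beta_init_j|, 1e-8)`; the floor keeps near-zero initial
#' coefficients heavily but finitely penalised.
#'
#' @param initial A `"ral_initial"` object or a numeric coefficient vector.
#' @return Positive finite vector of penalty weights.
#' @export
penalty_weights <- function(initial) {
  b <- if (inherits(initial, "ral_initial")) initial$beta else as.numeric(initial)
  1 / pmax(abs(b), .penalty_floor)
}

#' Entry point of the regularisation path
#'
#' Smallest penalty level at which every penalised coefficient is zero:
#' `max_j |z_j' W (y - ybar_w)| / (n * mix * v_j)` over standardized
#' columns `z_j`. Returns 0 when the weighted-centered response is
#' identically zero.
#'
#' @param X,y Data. @param w Observation weights (default all ones).
#' @param v Penalty weights (default all ones). @param mix Elastic-net
#'   mixing (1 = pure lasso).
#' @return Nonnegative scalar.
#' @export
lambda_max <- function(X, y, w = NULL, v = NULL, mix = 1) {
  d <- .validate_data(X, y)
  w <- w %||% rep(1, d$n)
  v <- v %||% rep(1, d$p)
  stopifnot(length(w) == d$n, length(v) == d$p, mix > 0, mix <= 1)
  std <- .wstd(d$X, d$y, w)
  if (length(std$keep) == 0L || max(abs(std$ytil)) < 1e-14) return(0)
  g <- abs(crossprod(std$Z, w * std$ytil)) / d$n
  out <- max(g / (mix * v[std$keep]))
  if (!is.finite(out)) 0 else out
}

# Core path solver: standardize, run C++ coordinate descent, back-transform.
.wal_core <- function(X, y, w, v, lambda, mix = 1, tol = 1e-7,
                      max_iter = 10000L, trace_obj = FALSE) {
  d <- .validate_data(X, y)
  stopifnot(length(w) == d$n, length(v) == d$p)
  if (any(w < 0 | w > 1)) stop("observation weights must lie in [0, 1]")
  if (all(w < 1e-10)) stop("degenerate weights: all observation weights ~ 0")
  if (any(!is.finite(v) | v <= 0)) stop("penalty weights must be positive and finite")
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  std <- .wstd(d$X, d$y, w)
  if (length(std$keep) < d$p) {
    warning(d$p - length(std$keep),
            " zero-variance column(s); coefficients set to 0")
  }
  nlam <- length(lambda)
  beta <- matrix(0, d$p, nlam, dimnames = list(colnames(d$X), NULL))
  if (length(std$keep) == 0L) {
    return(list(beta = beta, intercept = rep(std$ybar, nlam),
                converged = rep(TRUE, nlam), niter = rep(0L, nlam),
                obj_trace = vector("list", nlam)))
  }
  pf1 <- v[std$keep]
  pf2 <- v[std$keep]
  fit <- cd_path_cpp(std$Z, std$ytil, w, pf1, pf2, as.numeric(lambda),
                     mix, tol, as.integer(max_iter), trace_obj)
  beta[std$keep, ] <- fit$beta / std$s[std$keep]
  intercept <- std$ybar - drop(crossprod(beta, std$xbar))
  if (any(!fit$converged)) {
    j <- which(!fit$converged)
    kv <- kkt_violation(d$X, d$y, w, v, lambda[j[1L]],
                        intercept[j[1L]], beta[, j[1L]], mix)
    warning(sprintf(
      "coordinate descent hit max_iter at %d lambda value(s); max KKT violation %.3g",
      length(j), kv))
  }
  list(beta = beta, intercept = intercept, converged = fit$converged,
       niter = fit$niter,
       obj_trace = if (trace_obj) fit$obj_trace else vector("list", nlam))
}

#' Weighted adaptive lasso at a single penalty level
#'
#' Cyclic coordinate descent (exact univariate soft-threshold updates) for
#' the weighted elastic-net objective; see the package overview for the
#' exact objective. The working objective is nonincreasing over sweeps
#' (retrievable via `trace_obj = TRUE`) and the solution satisfies the KKT
#' conditions within `tol` (see [kkt_violation()]).
#'
#' @param X,y Data. @param w Observation weights in \[0, 1\].
#' @param v Positive penalty weights. @param lambda Nonnegative penalty.
#' @param mix Elastic-net mixing in (0, 1]; 1 is the pure lasso.
#' @param tol,max_iter Convergence controls.
#' @param trace_obj Record the objective after every sweep.
#' @return List with `intercept`, `beta` (exact zeros possible),
#'   `converged`, `niter`, `obj_trace`.
#' @export
fit_weighted_adaptive_lasso <- function(X, y, w, v, lambda, mix = 1,
                                        tol = 1e-7, max_iter = 10000L,
                                        trace_obj = FALSE) {
  stopifnot(length(lambda) == 1L)
  fit <- .wal_core(X, y, w, v, lambda, mix, tol, max_iter, trace_obj)
  list(intercept = fit$intercept[1L], beta = fit$beta[, 1L],
       converged = fit$converged[1L], niter = fit$niter[1L],
       obj_trace = fit$obj_trace[[1L]])
}

#' KKT violation of a candidate solution
#'
#' Largest violation of the stationarity conditions of the weighted
#' elastic-net objective, checked in the standardized coordinates the
#' penalty is defined in (including the unpenalised intercept): for a zero
#' coefficient the gradient must not exceed `lambda * mix * v_j` in
#' magnitude; for a nonzero coefficient the subgradient equation must hold.
#'
#' @inheritParams fit_weighted_adaptive_lasso
#' @param intercept,beta Candidate solution (original scale).
#' @return Nonnegative scalar (0 at an exact solution).
#' @export
kkt_violation <- function(X, y, w, v, lambda, intercept, beta, mix = 1) {
  d <- .validate_data(X, y)
  std <- .wstd(d$X, d$y, w)
  gam <- beta[std$keep] * std$s[std$keep]
  r <- std$ytil - drop(std$Z %*% gam)
  g0 <- drop(crossprod(std$Z, w * r)) / d$n
  vk <- v[std$keep]
  viol_int <- abs(sum(w * (d$y - intercept - drop(d$X %*% beta)))) / d$n
  zero <- gam == 0
  viol <- numeric(length(gam))
  viol[zero] <- pmax(0, abs(g0[zero]) - lambda * mix * vk[zero])
  nz <- !zero
  if (any(nz)) {
    viol[nz] <- abs(-g0[nz] + lambda * (1 - mix) * vk[nz] * gam[nz] +
                      lambda * mix * vk[nz] * sign(gam[nz]))
  }
  max(viol_int, viol)
}

# Shared pipeline behind fit_ral and fit_baseline: lambda path, CV, final
# path fit, model assembly.
.penalized_fit <- function(X, y, w, v, mix, method, cv_folds, seed,
                           nlambda, lambda_min_ratio, weights_obj = NULL,
                           initial = NULL, config = NULL,
                           tol = 1e-7, max_iter = 10000L) {
  d <- .validate_data(X, y)
  lmax <- lambda_max(d$X, d$y, w, v, mix)
  ratio <- lambda_min_ratio %||% if (d$p >= d$n) 0.01 else 0.001
  path <- if (lmax > 0) {
    exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
  } else {
    0
  }
  folds <- kfold_split(d$n, cv_folds, seed)
  cv <- cross_validate(d$X, d$y, w, v, path, K = cv_folds, foldid = folds,
                       mix = mix, tol = tol, max_iter = max_iter)
  fit <- .wal_core(d$X, d$y, w, v, path, mix, tol, max_iter)
  sel <- which(path == cv$lambda_selected)[1L]
  beta <- fit$beta[, sel]
  structure(list(method = method, intercept = fit$intercept[sel],
                 beta = beta, nonzero = which(beta != 0),
                 weights = weights_obj,
                 w = w, v = v, mix = mix,
                 lambda = cv$lambda_selected, lambda_path = path,
                 cv_errors = cv$mean_cv_error, cv_se = cv$se_cv_error,
                 fold_assignments = cv$fold_assignments,
                 path_beta = fit$beta, path_intercept = fit$intercept,
                 initial = initial, config = config,
                 n = d$n, p = d$p),
            class = "ral_model")
}

.muffle_clamp <- function(expr) {
  withCallingHandlers(expr, ralasso_clamp_warning = function(wng) {
    invokeRestart("muffleWarning")
  })
}

#' Fit the robust adaptive lasso
#'
#' Full pipeline: initial estimate (Tukey bisquare M when n > p, otherwise
#' cross-validated ridge), Pearson-residual observation weights, adaptive
#' penalty weights `1/max(|beta_init|, 1e-8)`, a 100-point log-spaced
#' penalty path from [lambda_max()] down, K-fold cross-validation of the
#' weighted held-out prediction error, and a final path fit at the selected
#' penalty. Deterministic given `seed`.
#'
#' @param X Design matrix (n x p). @param y Response vector.
#' @param config A [weight_config()].
#' @param cv_folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment (and nothing else).
#' @param nlambda Path length. @param lambda_min_ratio Smallest path value
#'   as a fraction of [lambda_max()]; defaults to 0.001 (0.01 when p >= n).
#' @param initial Optional `"ral_initial"` to reuse.
#' @param alpha_grid Optional numeric grid over the downweighting strength;
#'   when supplied, each alpha is cross-validated and the minimiser kept.
#' @return Object of class `"ral_model"`; coefficients contain exact zeros.
#' @seealso [fit_baseline()], [predict.ral_model()]
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(100 * 8), 100)
#' y <- drop(X %*% c(3, 1.5, 0, 0, 2, 0, 0, 0)) + rnorm(100)
#' fit <- fit_ral(X, y, seed = 1)
#' coef(fit)
fit_ral <- function(X, y, config = weight_config(), cv_folds = 10L,
                    seed = 1L, nlambda = 100L, lambda_min_ratio = NULL,
                    initial = NULL, alpha_grid = NULL) {
  d <- .validate_data(X, y)
  if (is.null(initial)) {
    initial <- if (d$n > d$p) {
      fit_tukey_m(d$X, d$y)
    } else {
      fit_ridge_initial(d$X, d$y, "cv", nfolds = cv_folds,
                        seed = derive_seeds(seed, 2L)[2L])
    }
  }
  stopifnot(inherits(initial, "ral_initial"))
  v <- penalty_weights(initial)

  weights_for <- function(cfg, fitted_values = NULL) {
    if (cfg$mode == "residual") {
      res <- if (is.null(fitted_values)) {
        d$y - initial$intercept - drop(d$X %*% initial$beta)
      } else {
        d$y - fitted_values
      }
      scale <- 1.4826 * median(abs(res - median(res)))
      if (scale <= 1e-10) scale <- max(sd(res), 1e-8)
      .muffle_clamp(compute_weights(res / scale,
                                    model_distribution("normal", c(0, 1)),
                                    cfg))
    } else {
      .muffle_clamp(compute_weights(
        d$y, fit_model_distribution(d$y, cfg$family), cfg))
    }
  }

  fit_one <- function(cfg) {
    wobj <- weights_for(cfg)
    .penalized_fit(d$X, d$y, wobj$w, v, mix = 1, method = "ral",
                   cv_folds = cv_folds, seed = seed, nlambda = nlambda,
                   lambda_min_ratio = lambda_min_ratio,
                   weights_obj = wobj, initial = initial, config = cfg)
  }

  if (!is.null(alpha_grid)) {
    fits <- lapply(alpha_grid, function(a) {
      cfg <- config
      cfg$alpha <- a
      fit_one(cfg)
    })
    best <- which.min(vapply(fits, function(f) min(f$cv_errors), 0))
    model <- fits[[best]]
    model$alpha_grid <- alpha_grid
    config <- model$config
  } else {
    model <- fit_one(config)
  }

  if (isTRUE(config$refine) && config$mode == "residual") {
    for (it in seq_len(config$max_refine)) {
      fitted <- model$intercept + drop(d$X %*% model$beta)
      wobj <- weights_for(config, fitted_values = fitted)
      if (max(abs(wobj$w - model$weights$w)) < config$refine_tol) break
      model <- .penalized_fit(d$X, d$y, wobj$w, v, mix = 1, method = "ral",
                              cv_folds = cv_folds, seed = seed,
                              nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio,
                              weights_obj = wobj, initial = initial,
                              config = config)
    }
  }
  model
}

#' Baseline penalised fits
#'
#' Lasso, adaptive lasso and elastic net as special cases of the same
#' solver: all observation weights 1; penalty weights 1 (lasso, elastic
#' net) or adaptive from the initial estimator; elastic net adds the
#' quadratic term with mixing `enet_mix` (1 reduces to the lasso).
#'
#' @inheritParams fit_ral
#' @param method One of `"lasso"`, `"adaptive_lasso"`, `"elastic_net"`.
#' @param enet_mix Elastic-net mixing parameter in (0, 1].
#' @return Object of class `"ral_model"` with all observation weights 1.
#' @export
fit_baseline <- function(X, y, method = c("lasso", "adaptive_lasso",
                                          "elastic_net"),
                         cv_folds = 10L, seed = 1L, enet_mix = 0.5,
                         nlambda = 100L, lambda_min_ratio = NULL,
                         initial = NULL) {
  method <- match.arg(method)
  d <- .validate_data(X, y)
  w <- rep(1, d$n)
  if (method == "adaptive_lasso") {
    if (is.null(initial)) {
      initial <- if (d$n > d$p) {
        fit_tukey_m(d$X, d$y)
      } else {
        fit_ridge_initial(d$X, d$y, "cv", nfolds = cv_folds,
                          seed = derive_seeds(seed, 2L)[2L])
      }
    }
    v <- penalty_weights(initial)
  } else {
    v <- rep(1, d$p)
  }
  mix <- if (method == "elastic_net") {
    stopifnot(enet_mix > 0, enet_mix <= 1)
    enet_mix
  } else {
    1
  }
  .penalized_fit(d$X, d$y, w, v, mix = mix, method = method,
                 cv_folds = cv_folds, seed = seed, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio, initial = initial)
}

#' Predict from a fitted model
#'
#' @param object A `"ral_model"`.
#' @param newx Matrix with the same number of columns as the training
#'   design.
#' @param ... Unused.
#' @return Numeric vector `intercept + newx %*% beta`.
#' @export
predict.ral_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$beta)) {
    stop(sprintf("column-count mismatch: newx has %d columns, model expects %d",
                 ncol(newx), length(object$beta)))
  }
  drop(object$intercept + newx %*% object$beta)
}

#' @export
coef.ral_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
print.ral_model <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, p = %d\n", x$method, x$n, x$p))
  cat(sprintf("  lambda = %.5g (path of %d), nonzero coefficients: %d\n",
              x$lambda, length(x$lambda_path), length(x$nonzero)))
  if (!is.null(x$weights) && inherits(x$weights, "ral_weights")) {
    cat(sprintf("  observation weights: min %.3g, %d below 0.5\n",
                min(x$weights$w), sum(x$weights$w < 0.5)))
  }
  invisible(x)
}
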