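# Independent oracles used across the suite. None of these call the
# package's coordinate-descent solver.

# Weighted least squares with intercept, closed form.
wls_oracle <- function(X, y, w) {
  A <- cbind(1, X)
  b <- solve(crossprod(A, A * w), crossprod(A, w * y))
  list(intercept = b[1L], beta = drop(b[-1L]))
}

# Exact minimiser of the weighted elastic-net objective
#   (1/2n) sum w_i (y_i - b0 - x_i'beta)^2
#     + lambda sum_j v_j (mix |gamma_j| + (1-mix)/2 gamma_j^2),
# gamma_j = beta_j * weighted sd of column j (penalty on the standardized
# scale, the package's stated convention), by enumeration of the 3^p sign
# patterns and solving the stationarity system of each (feasible only for
# p <= 3, which is all the oracle tests need). Independent of the
# coordinate-descent path.
enet_exact_oracle <- function(X, y, w, v, lambda, mix = 1) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(p <= 3L)
  sw <- sum(w)
  xbar <- colSums(X * w) / sw
  ybar <- sum(w * y) / sw
  Xc <- sweep(X, 2L, xbar)
  sj <- sqrt(colSums(Xc^2 * w) / sw)
  v <- v * sj                      # fold the standardization into the L1 part
  v2 <- v * sj                     # and quadratically into the L2 part
  yc <- y - ybar
  G <- crossprod(Xc, Xc * w) / n          # (1/n) X'WX
  g <- drop(crossprod(Xc, w * yc)) / n    # (1/n) X'Wy
  objective <- function(beta) {
    r <- yc - drop(Xc %*% beta)
    sum(w * r^2) / (2 * n) +
      lambda * sum(mix * v * abs(beta) + 0.5 * (1 - mix) * v2 * beta^2)
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), p)))
  best <- NULL; best_obj <- Inf
  for (i in seq_len(nrow(signs))) {
    s <- signs[i, ]
    S <- which(s != 0L)
    beta <- numeric(p)
    if (length(S)) {
      M <- G[S, S, drop = FALSE] +
        diag(lambda * (1 - mix) * v2[S], length(S))
      rhs <- g[S] - lambda * mix * v[S] * s[S]
      bS <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(bS)) next
      if (any(sign(bS) != s[S])) next
      beta[S] <- bS
    }
    grad0 <- g - drop(G %*% beta)
    Z <- setdiff(seq_len(p), S)
    if (length(Z) && any(abs(grad0[Z]) > lambda * mix * v[Z] + 1e-10)) next
    ob <- objective(beta)
    if (ob < best_obj) { best_obj <- ob; best <- beta }
  }
  stopifnot(!is.null(best))
  list(intercept = ybar - sum(best * xbar), beta = best, objective = best_obj)
}

# Small seeded regression instance.
gen_instance <- function(n, p, seed = 1, beta = NULL, sd = 1, r = 0) {
  X <- generate_design(n, p, r, seed = seed)
  beta <- beta %||% rep_len(c(2, -1, 0.5), p)
  eps <- with_seed_test(seed + 1000L, rnorm(n, sd = sd))
  list(X = X, y = drop(X %*% beta) + eps, beta = beta)
}

# Local seed helper for test fixtures (mirrors the package-internal one).
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
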