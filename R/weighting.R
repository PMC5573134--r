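# Pearson-residual observation weighting.
#
# An i.i.d. sample is compared against an assumed model distribution F_theta.
# In the left tail (F_theta <= q) the ratio F_n/F_theta - 1 measures the
# mismatch of empirical and model mass; in the right tail (F_theta >= 1-q)
# the survival functions play the same role; the centre is left alone.
# Large residuals are mapped to small multiplicative weights by
# H(tau) = exp(-alpha * tau^2).

#' Weighting configuration
#'
#' Bundles the tuning constants of the Pearson-residual weighting scheme.
#'
#' @param q Tail fraction in (0, 0.5]. Observations whose model CDF value
#'   falls in the outer `q` mass of either tail are candidates for
#'   downweighting; everything in between keeps weight 1.
#' @param alpha Positive downweighting strength of `H(tau) = exp(-alpha
#'   tau^2)`. Larger values downweight more aggressively; the simulation
#'   studies use values in (0.005, 0.05).
#' @param mode `"residual"` builds weights from standardized residuals of an
#'   initial robust fit compared against a standard normal; `"response"`
#'   builds them from the raw response compared against a maximum-likelihood
#'   fit of `family` (useful for skewed responses, e.g. a gamma model).
#' @param family Model family used in `mode = "response"`.
#' @param refine If `TRUE`, [fit_ral()] re-computes weights from its own
#'   residuals for up to `max_refine` rounds (stopping when the largest
#'   weight change is below `refine_tol`). Off by default: weights are
#'   computed once from the initial estimator and held fixed.
#' @param max_refine,refine_tol Refinement loop controls.
#' @return An object of class `"weight_config"`.
#' @seealso [compute_weights()], [fit_ral()]
#' @export
#' @examples
#' weight_config(q = 0.25, alpha = 0.05)
weight_config <- function(q = 0.25, alpha = 0.05,
                          mode = c("residual", "response"),
                          family = c("normal", "gamma"),
                          refine = FALSE, max_refine = 5L,
                          refine_tol = 1e-4) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q))
  if (q <= 0 || q > 0.5) stop("q must lie in (0, 0.5]")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(q = q, alpha = alpha, mode = mode, family = family,
                 refine = isTRUE(refine), max_refine = as.integer(max_refine),
                 refine_tol = refine_tol),
            class = "weight_config")
}

#' Model distribution for weighting
#'
#' A parametric reference distribution whose CDF and survival function are
#' compared against their empirical counterparts.
#'
#' @param family `"normal"` or `"gamma"`.
#' @param parameters Numeric vector: `c(mean, sd)` for normal (sd > 0),
#'   `c(shape, rate)` for gamma (both > 0).
#' @return Object of class `"model_distribution"`.
#' @export
#' @examples
#' m <- model_distribution("normal", c(0, 1))
#' model_cdf(m, 0)           # 0.5
model_distribution <- function(family = c("normal", "gamma"), parameters) {
  family <- match.arg(family)
  parameters <- as.numeric(parameters)
  if (length(parameters) != 2L || any(!is.finite(parameters))) {
    stop("parameters must be two finite numbers")
  }
  if (family == "normal" && parameters[2L] <= 0) stop("sd must be > 0")
  if (family == "gamma" && any(parameters <= 0)) {
    stop("gamma shape and rate must be > 0")
  }
  structure(list(family = family, parameters = parameters),
            class = "model_distribution")
}

#' @rdname model_distribution
#' @param model A `"model_distribution"`.
#' @param y Numeric vector of evaluation points.
#' @export
model_cdf <- function(model, y) {
  stopifnot(inherits(model, "model_distribution"))
  switch(model$family,
         normal = pnorm(y, model$parameters[1L], model$parameters[2L]),
         gamma  = pgamma(y, shape = model$parameters[1L],
                         rate = model$parameters[2L]))
}

#' @rdname model_distribution
#' @export
model_survival <- function(model, y) {
  stopifnot(inherits(model, "model_distribution"))
  switch(model$family,
         normal = pnorm(y, model$parameters[1L], model$parameters[2L],
                        lower.tail = FALSE),
         gamma  = pgamma(y, shape = model$parameters[1L],
                         rate = model$parameters[2L], lower.tail = FALSE))
}

#' Maximum-likelihood fit of a model distribution
#'
#' Normal: sample mean and ML standard deviation. Gamma: shape solves
#' `log(s) - digamma(s) = log(mean(x)) - mean(log(x))` (Newton iteration from
#' the standard approximation), rate = shape / mean.
#'
#' @param values Numeric sample (gamma requires strictly positive values).
#' @param family `"normal"` or `"gamma"`.
#' @return A `"model_distribution"`.
#' @export
fit_model_distribution <- function(values, family = c("normal", "gamma")) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("need at least two finite values")
  }
  if (family == "normal") {
    m <- mean(values)
    s <- sqrt(mean((values - m)^2))
    if (s <= 0) stop("degenerate sample: zero variance")
    return(model_distribution("normal", c(m, s)))
  }
  if (any(values <= 0)) stop("gamma family requires positive values")
  mlog <- log(mean(values)) - mean(log(values))
  if (mlog <= 0) stop("degenerate sample for gamma fit")
  s <- (3 - mlog + sqrt((mlog - 3)^2 + 24 * mlog)) / (12 * mlog)
  for (it in seq_len(50L)) {
    f <- log(s) - digamma(s) - mlog
    fp <- 1 / s - trigamma(s)
    s_new <- s - f / fp
    if (!is.finite(s_new) || s_new <= 0) s_new <- s / 2
    if (abs(s_new - s) < 1e-10 * s) { s <- s_new; break }
    s <- s_new
  }
  model_distribution("gamma", c(s, s / mean(values)))
}

#' Empirical distribution and survival functions
#'
#' `empirical_cdf(values, y)` is the fraction of sample points `<= y`;
#' `empirical_survival(values, y)` the fraction `>= y`. For a sample point of
#' a tie-free sample the two sum to `1 + 1/n`.
#'
#' @param values Numeric sample (nonempty, finite).
#' @param y Evaluation points (vectorised).
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' empirical_cdf(c(1, 2, 3), 2)       # 2/3
#' empirical_survival(c(1, 2, 3), 2)  # 2/3
empirical_cdf <- function(values, y) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty sample")
  if (any(!is.finite(values))) stop("sample contains non-finite values")
  vs <- sort(values)
  findInterval(y, vs) / length(vs)
}

#' @rdname empirical_cdf
#' @export
empirical_survival <- function(values, y) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty sample")
  if (any(!is.finite(values))) stop("sample contains non-finite values")
  # #{x >= y} = #{-x <= -y}, counted by findInterval on the negated sample
  vs <- sort(-values)
  findInterval(-y, vs) / length(vs)
}

# Clamp model tail probabilities away from 0/1 before division. Extreme
# outliers otherwise yield 0 in the denominator; clamping produces the
# intended huge residual and hence weight ~ 0.
.clamp_eps <- 1e-12

.clamp_prob <- function(p, what) {
  bad <- p < .clamp_eps | p > 1 - .clamp_eps
  if (any(bad)) {
    warning(warningCondition(
      sprintf("%s numerically 0 or 1 for %d point(s); clamped to [1e-12, 1 - 1e-12]",
              what, sum(bad)),
      class = "ralasso_clamp_warning"))
    p <- pmin(pmax(p, .clamp_eps), 1 - .clamp_eps)
  }
  p
}

#' Pearson residual between empirical and model distributions
#'
#' Piecewise tail comparison at each point `y`: `F_n/F_theta - 1` where the
#' model CDF is at most `q`, `S_n/S_theta - 1` where it is at least `1 - q`,
#' and exactly 0 in the central region. Model probabilities numerically equal
#' to 0 or 1 are clamped to `[1e-12, 1 - 1e-12]` with a warning of class
#' `"ralasso_clamp_warning"`.
#'
#' @param values Numeric sample defining the empirical functions.
#' @param model A [model_distribution()].
#' @param y Evaluation points (vectorised).
#' @param q Tail fraction in (0, 0.5].
#' @return Numeric vector of residuals, each `>= -1`.
#' @export
#' @examples
#' m <- model_distribution("normal", c(0, 1))
#' pearson_residual(rnorm(50), m, 0, q = 0.25)  # central region: exactly 0
pearson_residual <- function(values, model, y, q) {
  stopifnot(is.numeric(q), length(q) == 1L)
  if (q <= 0 || q > 0.5) stop("q must lie in (0, 0.5]")
  Ft <- .clamp_prob(model_cdf(model, y), "model CDF")
  tau <- numeric(length(y))
  left <- Ft <= q
  right <- Ft >= 1 - q
  if (any(left)) {
    tau[left] <- empirical_cdf(values, y[left]) / Ft[left] - 1
  }
  if (any(right)) {
    St <- .clamp_prob(model_survival(model, y[right]), "model survival")
    tau[right] <- empirical_survival(values, y[right]) / St - 1
  }
  tau
}

#' Residual-adjustment (downweighting) function
#'
#' `H(tau) = exp(-alpha * tau^2)`: equals 1 at `tau = 0`, symmetric in `tau`,
#' decreasing in `|tau|`, always in (0, 1].
#'
#' @param tau Numeric residuals (vectorised).
#' @param alpha Positive constant; larger means stronger downweighting.
#' @return Weights in (0, 1].
#' @export
#' @examples
#' downweight_H(0, 0.05)    # 1
#' downweight_H(-1, 2.202)  # exp(-2.202) ~ 0.11
downweight_H <- function(tau, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0) stop("alpha must be positive")
  exp(-alpha * tau^2)
}

#' Observation weights from Pearson residuals
#'
#' Evaluates the Pearson residual of every entry of `u` against `model` and
#' maps tail residuals through [downweight_H()]. Observations whose model CDF
#' value lies strictly inside `(q, 1 - q)` keep weight exactly 1.
#'
#' @param u Numeric vector (standardized residuals in `mode = "residual"`,
#'   the raw response in `mode = "response"`); length >= 2, all finite.
#' @param model A [model_distribution()].
#' @param config A [weight_config()].
#' @return Object of class `"ral_weights"`: list with components `w`
#'   (weights in (0, 1]), `tau`, `F_n`, `F_theta`, `values` and `config`.
#' @export
#' @examples
#' u <- c(-0.1, 0, 0.1, -50)
#' cw <- suppressWarnings(
#'   compute_weights(u, model_distribution("normal", c(0, 1)),
#'                   weight_config(q = 0.25, alpha = 1)))
#' cw$w   # the gross outlier gets weight ~ 0
compute_weights <- function(u, model, config = weight_config()) {
  stopifnot(inherits(config, "weight_config"),
            inherits(model, "model_distribution"))
  u <- as.numeric(u)
  if (length(u) < 2L) stop("need at least two observations")
  bad <- which(!is.finite(u))
  if (length(bad)) {
    stop("non-finite entries in u at indices: ",
         paste(head(bad, 10L), collapse = ", "))
  }
  tau <- pearson_residual(u, model, u, config$q)
  w <- downweight_H(tau, config$alpha)
  Ft <- model_cdf(model, u)
  central <- Ft > config$q & Ft < 1 - config$q
  w[central] <- 1  # H(0) = 1 already; keep the central branch exact
  structure(list(w = w, tau = tau, F_n = empirical_cdf(u, u),
                 F_theta = Ft, values = u, config = config),
            class = "ral_weights")
}

#' @export
print.ral_weights <- function(x, ...) {
  cat(sprintf("Pearson-residual weights: n = %d, q = %g, alpha = %g\n",
              length(x$w), x$config$q, x$config$alpha))
  cat(sprintf("  weights < 0.5: %d; min weight = %.4g\n",
              sum(x$w < 0.5), min(x$w)))
  invisible(x)
}
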