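#' Conjugate model specifications
#'
#' A `gof_model` bundles a likelihood family with a conjugate prior (or a
#' point-mass "prior"), and is the unit both of the *statistical* model used
#' to analyse data and of the *probabilistic* model used to generate data.
#' Three families are supported:
#'
#' * `poisson_model(shape, rate)` — Poisson likelihood, Gamma(shape, rate)
#'   prior on the rate \eqn{\lambda} (shape/rate parameterization, so the
#'   prior mean is `shape/rate`).
#' * `bernoulli_model(shape1, shape2)` — Bernoulli likelihood,
#'   Beta(shape1, shape2) prior on the success probability \eqn{p}.
#' * `normal_model(mu0, kappa0, a0, b0)` — Normal likelihood with unknown
#'   mean and variance under the conjugate normal–inverse-gamma prior:
#'   \eqn{\sigma^2 \sim \mathrm{InvGamma}(a_0, b_0)} and
#'   \eqn{\mu \mid \sigma^2 \sim N(\mu_0, \sigma^2/\kappa_0)}.
#' * `dirac_model(family, theta)` — a point mass at a fixed parameter value,
#'   used as the data-generating "prior" in Dirac scenarios.
#'
#' Parameter values (`theta`) are plain named numeric vectors: `c(lambda=)`,
#' `c(p=)`, or `c(mu=, sigma2=)`.
#'
#' @param shape,rate Gamma prior hyperparameters (both > 0).
#' @param shape1,shape2 Beta prior hyperparameters (both > 0).
#' @param mu0 Prior location of the mean.
#' @param kappa0 Prior precision scale (> 0); the conditional prior variance
#'   of the mean is `sigma2 / kappa0`.
#' @param a0,b0 Inverse-gamma shape and scale for the variance (both > 0).
#' @param family One of `"poisson"`, `"bernoulli"`, `"normal"`.
#' @param theta A parameter value in the family's parameter space.
#' @return An object of class `gof_model`.
#' @examples
#' m <- poisson_model(2, 1)
#' posterior_update(m, c(1, 2))
#' @name gof_model
NULL

new_gof_model <- function(family, prior, dirac = NULL) {
  structure(list(family = family, prior = prior, dirac = dirac),
            class = "gof_model")
}

#' @rdname gof_model
#' @export
poisson_model <- function(shape = 1, rate = 1) {
  stopifnot(is.numeric(shape), is.numeric(rate), shape > 0, rate > 0)
  new_gof_model("poisson", list(shape = shape, rate = rate))
}

#' @rdname gof_model
#' @export
bernoulli_model <- function(shape1 = 1, shape2 = 1) {
  stopifnot(shape1 > 0, shape2 > 0)
  new_gof_model("bernoulli", list(shape1 = shape1, shape2 = shape2))
}

#' @rdname gof_model
#' @export
normal_model <- function(mu0 = 0, kappa0 = 1, a0 = 2, b0 = 1) {
  stopifnot(is.finite(mu0), kappa0 > 0, a0 > 0, b0 > 0)
  new_gof_model("normal", list(mu0 = mu0, kappa0 = kappa0, a0 = a0, b0 = b0))
}

#' @rdname gof_model
#' @export
dirac_model <- function(family, theta) {
  family <- match.arg(family, c("poisson", "bernoulli", "normal"))
  check_theta(family, theta)
  new_gof_model(family, prior = NULL, dirac = theta)
}

#' @export
print.gof_model <- function(x, ...) {
  if (is_dirac(x)) {
    cat(sprintf("<gof_model> %s likelihood, point-mass prior at (%s)\n",
                x$family, paste(signif(x$dirac, 4), collapse = ", ")))
  } else {
    hp <- paste(names(x$prior), signif(unlist(x$prior), 5),
                sep = "=", collapse = ", ")
    cat(sprintf("<gof_model> %s likelihood, conjugate prior (%s)\n",
                x$family, hp))
  }
  invisible(x)
}

is_dirac <- function(model) !is.null(model$dirac)

check_theta <- function(family, theta) {
  ok <- switch(family,
    poisson   = length(theta) == 1 && is.finite(theta) && theta[[1]] > 0,
    bernoulli = length(theta) == 1 && is.finite(theta) &&
                theta[[1]] >= 0 && theta[[1]] <= 1,
    normal    = length(theta) == 2 && all(is.finite(theta)) && theta[[2]] > 0
  )
  if (!isTRUE(ok)) {
    stop("invalid parameter value for family '", family, "': ",
         paste(theta, collapse = ", "), call. = FALSE)
  }
  invisible(theta)
}

check_data <- function(family, x) {
  if (length(x) < 1 || anyNA(x)) {
    stop("data must be a non-empty numeric vector without NAs", call. = FALSE)
  }
  if (family %in% c("poisson", "bernoulli")) {
    if (any(x < 0) || any(x != floor(x))) {
      stop("'", family, "' data must be nonnegative integers", call. = FALSE)
    }
    if (family == "bernoulli" && any(x > 1)) {
      stop("'bernoulli' data must lie in {0, 1}", call. = FALSE)
    }
  }
  invisible(x)
}

#' Conjugate posterior update
#'
#' Returns the posterior of the model's parameters given i.i.d. observations,
#' as a `gof_model` of the same family (conjugacy closure).  Poisson–Gamma:
#' `(a + sum(x), b + n)`.  Bernoulli–Beta: `(a + sum(x), b + n - sum(x))`.
#' Normal–inverse-gamma: the standard closed-form update of
#' `(mu0, kappa0, a0, b0)`.
#'
#' @param model A proper (non-Dirac) `gof_model`.
#' @param x Numeric vector of observations from the model's family.
#' @return A `gof_model` holding the posterior hyperparameters.
#' @export
posterior_update <- function(model, x) {
  stopifnot(inherits(model, "gof_model"))
  if (is_dirac(model)) {
    stop("posterior update is undefined for a point-mass (Dirac) prior",
         call. = FALSE)
  }
  if (length(x) == 0) return(model)
  check_data(model$family, x)
  n <- length(x)
  s <- sum(x)
  switch(model$family,
    poisson = poisson_model(model$prior$shape + s, model$prior$rate + n),
    bernoulli = bernoulli_model(model$prior$shape1 + s,
                                model$prior$shape2 + n - s),
    normal = {
      p <- model$prior
      xbar <- mean(x)
      kn <- p$kappa0 + n
      mun <- (p$kappa0 * p$mu0 + n * xbar) / kn
      an <- p$a0 + n / 2
      bn <- p$b0 + 0.5 * sum((x - xbar)^2) +
        p$kappa0 * n * (xbar - p$mu0)^2 / (2 * kn)
      normal_model(mun, kn, an, bn)
    }
  )
}

#' Draw parameter values from a model's prior (or posterior)
#'
#' Draws from the distribution a `gof_model` places on its parameters; a
#' Dirac model returns its fixed value.  For the normal family each draw is
#' `(mu, sigma2)` from the normal–inverse-gamma law.
#'
#' @param model A `gof_model` (prior or the output of [posterior_update()]).
#' @param n Number of draws.
#' @return For `n = 1` a named numeric parameter vector; for `n > 1` a matrix
#'   with one row per draw.
#' @export
sample_theta <- function(model, n = 1) {
  stopifnot(inherits(model, "gof_model"), n >= 1)
  if (is_dirac(model)) {
    th <- theta_matrix(model$family, n, model$dirac)
    return(if (n == 1) th[1, ] else th)
  }
  p <- model$prior
  th <- switch(model$family,
    poisson = cbind(lambda = stats::rgamma(n, p$shape, rate = p$rate)),
    bernoulli = cbind(p = stats::rbeta(n, p$shape1, p$shape2)),
    normal = {
      sigma2 <- p$b0 / stats::rgamma(n, p$a0)    # InvGamma(a0, b0)
      mu <- stats::rnorm(n, p$mu0, sqrt(sigma2 / p$kappa0))
      cbind(mu = mu, sigma2 = sigma2)
    }
  )
  if (n == 1) th[1, ] else th
}

theta_matrix <- function(family, n, theta) {
  m <- matrix(rep(as.numeric(theta), each = n), nrow = n)
  colnames(m) <- switch(family, poisson = "lambda", bernoulli = "p",
                        normal = c("mu", "sigma2"))
  m
}

#' Simulate data from a likelihood family
#'
#' @param family One of `"poisson"`, `"bernoulli"`, `"normal"`.
#' @param theta Parameter value (named or unnamed): `lambda`, `p`, or
#'   `c(mu, sigma2)`.
#' @param n Number of i.i.d. observations (>= 1).
#' @return Numeric vector of length `n`.
#' @export
sample_data <- function(family, theta, n) {
  stopifnot(n >= 1)
  check_theta(family, theta)
  theta <- as.numeric(theta)
  switch(family,
    poisson = stats::rpois(n, theta[1]),
    bernoulli = stats::rbinom(n, 1, theta[1]),
    normal = stats::rnorm(n, theta[1], sqrt(theta[2]))
  )
}

# K replicate datasets of size n as a K x n matrix; theta either a single
# parameter vector (shared) or a K-row matrix (one parameter per replicate).
sample_data_matrix <- function(family, theta, K, n) {
  if (is.matrix(theta)) {
    stopifnot(nrow(theta) == K)
    # column-major fill: element (i, j) uses theta[i, ]
    switch(family,
      poisson = matrix(stats::rpois(K * n, rep(theta[, 1], n)), nrow = K),
      bernoulli = matrix(stats::rbinom(K * n, 1, rep(theta[, 1], n)), nrow = K),
      normal = matrix(stats::rnorm(K * n, rep(theta[, 1], n),
                                   rep(sqrt(theta[, 2]), n)), nrow = K)
    )
  } else {
    matrix(sample_data(family, theta, K * n), nrow = K)
  }
}

#' Maximum likelihood estimate, optionally on a subset
#'
#' Poisson: subset mean.  Bernoulli: subset proportion.  Normal: subset mean
#' and the maximum-likelihood variance (denominator `m`, not `m - 1`).  A
#' Poisson estimate of 0 or a Bernoulli proportion in {0, 1} is a boundary
#' MLE: it is returned with attribute `boundary = TRUE` so that callers
#' needing a non-degenerate plug-in value can refuse it.
#'
#' @param family Likelihood family.
#' @param x Observation vector.
#' @param subset Integer indices to use (default: all observations).
#' @return Named parameter vector with a logical `boundary` attribute.
#' @export
mle <- function(family, x, subset = seq_along(x)) {
  if (length(subset) == 0) stop("empty subset in mle()", call. = FALSE)
  x <- x[subset]
  check_data(family, x)
  m <- length(x)
  out <- switch(family,
    poisson = c(lambda = mean(x)),
    bernoulli = c(p = mean(x)),
    normal = c(mu = mean(x), sigma2 = sum((x - mean(x))^2) / m)
  )
  boundary <- switch(family,
    poisson = out[["lambda"]] == 0,
    bernoulli = out[["p"]] %in% c(0, 1),
    normal = out[["sigma2"]] == 0
  )
  attr(out, "boundary") <- boundary
  out
}

# Uniformly random floor(n/2)-subset without replacement.
half_sample_indices <- function(n) {
  sample.int(n, size = max(1L, n %/% 2L))
}

#' Randomized cumulative distribution function
#'
#' The (randomized) probability integral transform underlying normalized and
#' uniformized data.  Continuous families return \eqn{F_\theta(x)}; discrete
#' families return \eqn{F_\theta(x-1) + u\,(F_\theta(x) - F_\theta(x-1))},
#' where \eqn{F_\theta(x-1)} is the CDF at the largest support point strictly
#' below `x` (and \eqn{F(-1) = 0}).  If `x ~ f(. | theta)` and
#' `u ~ U(0, 1)` independently, the output is exactly U(0, 1).
#'
#' Vectorized over `x` and `u`; `theta` may also be a matrix with one row per
#' element of `x` for per-observation parameter values.
#'
#' @param family Likelihood family.
#' @param theta Parameter value (or matrix of values).
#' @param x Observed value(s).
#' @param u Uniform draw(s) in `[0, 1]` (recycled; ignored for continuous
#'   families).
#' @return Values in `[0, 1]`.
#' @export
cdf_randomized <- function(family, theta, x, u = 0.5) {
  if (!is.matrix(theta)) check_theta(family, theta)
  stopifnot(all(u >= 0 & u <= 1))
  th1 <- if (is.matrix(theta)) theta[, 1] else as.numeric(theta)[1]
  switch(family,
    poisson = stats::ppois(x - 1, th1) + u * stats::dpois(x, th1),
    bernoulli = {
      lower <- ifelse(x >= 1, 1 - th1, 0)
      atom <- ifelse(x >= 1, th1, 1 - th1)
      lower + u * atom
    },
    normal = {
      s2 <- if (is.matrix(theta)) theta[, 2] else as.numeric(theta)[2]
      stats::pnorm(x, th1, sqrt(s2))
    }
  )
}

#' Model mean and variance
#'
#' Closed-form mean and variance of one observation given `theta`, used by
#' the centered discrepancy functions.
#'
#' @inheritParams cdf_randomized
#' @return Named numeric vector `c(mean, variance)` (or a two-column matrix
#'   when `theta` is a matrix of parameter rows).
#' @export
model_moments <- function(family, theta) {
  th <- if (is.matrix(theta)) theta else matrix(as.numeric(theta), nrow = 1)
  out <- switch(family,
    poisson = cbind(mean = th[, 1], variance = th[, 1]),
    bernoulli = cbind(mean = th[, 1], variance = th[, 1] * (1 - th[, 1])),
    normal = cbind(mean = th[, 1], variance = th[, 2])
  )
  if (is.matrix(theta)) out
  else c(mean = unname(out[1, 1]), variance = unname(out[1, 2]))
}

# Pointwise log density, vectorized over x (single theta).
log_density <- function(family, theta, x) {
  theta <- as.numeric(theta)
  switch(family,
    poisson = stats::dpois(x, theta[1], log = TRUE),
    bernoulli = stats::dbinom(x, 1, theta[1], log = TRUE),
    normal = stats::dnorm(x, theta[1], sqrt(theta[2]), log = TRUE)
  )
}

#' Frequentist parameter draw for the Poisson family
#'
#' The frequentist analogue of a single posterior draw: the rate is drawn on
#' the log scale from a normal distribution centred at `log(mean(x))` with
#' standard error `1/sqrt(sum(x))` — the intercept-only log-link Poisson GLM
#' standard error.  Only the Poisson family is supported.
#'
#' @param family Must be `"poisson"`.
#' @param x Observation vector with `sum(x) > 0`.
#' @return Named vector `c(lambda=)`.
#' @export
freq_theta_draw <- function(family, x) {
  if (family != "poisson") {
    stop("freq_theta_draw() supports only the poisson family", call. = FALSE)
  }
  check_data(family, x)
  if (sum(x) == 0) {
    stop("boundary estimate: sum(x) = 0 gives an infinite log-scale s.e.",
         call. = FALSE)
  }
  se <- 1 / sqrt(sum(x))
  c(lambda = exp(stats::rnorm(1, log(mean(x)), se)))
}
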