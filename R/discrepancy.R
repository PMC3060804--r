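#' Discrepancy function registry
#'
#' Discrepancy functions `d(X, theta)` quantify model–data disagreement;
#' test statistics are the special case that ignores `theta`.  The registry
#' covers the statistics used throughout the simulation harness:
#'
#' | name       | scale(s)          | needs theta | definition |
#' |------------|-------------------|-------------|------------|
#' | `mean`     | raw, normalized   | no  | sample mean |
#' | `variance` | raw, normalized   | no  | sample variance (denominator n-1) |
#' | `meanc`    | raw               | yes | sample mean minus model mean |
#' | `varc`     | raw               | yes | sample variance minus model variance |
#' | `maximum`  | raw, normalized   | no  | largest observation |
#' | `skewness` | normalized        | no  | standardized third sample moment |
#' | `kurtosis` | normalized        | no  | standardized fourth moment (raw, not excess) |
#' | `za`       | normalized        | no  | Zhang's likelihood-ratio EDF statistic |
#' | `loglik`   | raw               | yes | joint log likelihood at theta |
#'
#' `za`, `skewness` and `kurtosis` are only meaningful on the
#' normalized/uniformized scale; `meanc`, `varc` and `loglik` require a
#' parameter value.  Zhang's statistic is computed on the ascending-sorted
#' uniformized values \eqn{U_{(i)} = \Phi(y_{(i)})} as
#' \deqn{Z_A = -\sum_i \left[\frac{\log U_{(i)}}{n-i+0.5} +
#'   \frac{\log(1-U_{(i)})}{i-0.5}\right].}
#' Skewness and kurtosis use biased (moment) estimators; only the ordering
#' matters for p-values.
#'
#' @param name A registry name, or any name if `fn` is supplied.
#' @param input_scale `"raw"` (original data scale) or `"normalized"`
#'   (randomized-PIT + standard-normal-quantile scale, see
#'   [normalize_data()]).
#' @param fn Optional user discrepancy: a function `(x, theta, family)`
#'   returning a scalar, registered under `name` for this spec only.
#' @param needs_theta For a user `fn`: whether it requires a parameter value
#'   (default `FALSE`, i.e. a plain test statistic).
#' @return A `disc_spec` object.
#' @examples
#' compute_discrepancy(discrepancy_spec("mean"), c(1, 2, 3))
#' @export
discrepancy_spec <- function(name, input_scale = NULL, fn = NULL,
                             needs_theta = FALSE) {
  if (is.null(fn)) {
    name <- match.arg(name, names(.disc_registry))
    entry <- .disc_registry[[name]]
    if (is.null(input_scale)) input_scale <- entry$scales[1]
    input_scale <- match.arg(input_scale, c("raw", "normalized"))
    if (!input_scale %in% entry$scales) {
      stop("discrepancy '", name, "' is not defined on the ", input_scale,
           " scale", call. = FALSE)
    }
    needs_theta <- entry$needs_theta
  } else {
    stopifnot(is.function(fn))
    input_scale <- match.arg(input_scale, c("raw", "normalized"))
  }
  structure(list(name = name, input_scale = input_scale,
                 needs_theta = needs_theta, fn = fn),
            class = "disc_spec")
}

#' @export
print.disc_spec <- function(x, ...) {
  cat(sprintf("<disc_spec> %s on %s data%s\n", x$name, x$input_scale,
              if (x$needs_theta) " (uses theta)" else ""))
  invisible(x)
}

#' List available discrepancy functions
#'
#' @return A tibble with columns `name`, `scales`, `needs_theta`.
#' @export
list_discrepancies <- function() {
  tibble::tibble(
    name = names(.disc_registry),
    scales = vapply(.disc_registry, function(e)
      paste(e$scales, collapse = ","), character(1)),
    needs_theta = vapply(.disc_registry, function(e)
      e$needs_theta, logical(1))
  )
}

# ---- row-wise statistic kernels (X is a K x n matrix, one replicate/row) ----

row_vars <- function(X) {
  n <- ncol(X)
  if (n < 2) stop("variance needs at least 2 observations", call. = FALSE)
  m <- rowMeans(X)
  pmax(0, (rowSums(X^2) - n * m^2) / (n - 1))
}

row_max <- function(X) {
  out <- X[, 1]
  for (j in seq_len(ncol(X))[-1]) out <- pmax(out, X[, j])
  out
}

row_central_moment <- function(X, m, k) rowSums((X - m)^k) / ncol(X)

row_skewness <- function(X) {
  m <- rowMeans(X)
  m2 <- row_central_moment(X, m, 2)
  row_central_moment(X, m, 3) / m2^1.5
}

row_kurtosis <- function(X) {
  m <- rowMeans(X)
  m2 <- row_central_moment(X, m, 2)
  row_central_moment(X, m, 4) / m2^2
}

# Zhang's Z_A on normalized-scale rows.
row_za <- function(Y) {
  n <- ncol(Y)
  U <- stats::pnorm(Y)
  U <- pmin(pmax(U, .Machine$double.eps), 1 - .Machine$double.neg.eps)
  # row-wise ascending sort in one radix pass (much faster than apply/sort)
  Us <- if (n == 1) U else
    matrix(U[order(row(U), U, method = "radix")], nrow = nrow(U), byrow = TRUE)
  i <- seq_len(n)
  drop(-(log(Us) %*% (1 / (n - i + 0.5)) + log1p(-Us) %*% (1 / (i - 0.5))))
}

row_loglik <- function(X, theta, family) {
  th1 <- if (is.matrix(theta)) theta[, 1] else as.numeric(theta)[1]
  switch(family,
    poisson = log(th1) * rowSums(X) - ncol(X) * th1 - rowSums(lgamma(X + 1)),
    bernoulli = rowSums(X) * log(th1) + (ncol(X) - rowSums(X)) * log1p(-th1),
    normal = {
      s2 <- if (is.matrix(theta)) theta[, 2] else as.numeric(theta)[2]
      -0.5 * ncol(X) * log(2 * pi * s2) - rowSums((X - th1)^2) / (2 * s2)
    }
  )
}

# Dispatch a registry statistic over matrix rows.  theta may be a single
# parameter vector or a matrix with one parameter row per replicate row.
disc_rows <- function(spec, X, theta = NULL, family = NULL) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (spec$needs_theta && is.null(theta)) {
    stop("discrepancy '", spec$name, "' requires a parameter value",
         call. = FALSE)
  }
  if (!is.null(spec$fn)) {
    return(apply(X, 1, spec$fn, theta = theta, family = family))
  }
  switch(spec$name,
    mean = rowMeans(X),
    variance = row_vars(X),
    meanc = rowMeans(X) - mom_col(family, theta, "mean"),
    varc = row_vars(X) - mom_col(family, theta, "variance"),
    maximum = row_max(X),
    skewness = row_skewness(X),
    kurtosis = row_kurtosis(X),
    za = row_za(X),
    loglik = row_loglik(X, theta, family)
  )
}

mom_col <- function(family, theta, which) {
  mm <- model_moments(family, theta)
  if (is.matrix(mm)) mm[, which] else mm[[which]]
}

#' Compute a discrepancy value
#'
#' @param spec A [discrepancy_spec()].
#' @param x Numeric data vector, already on the scale `spec` expects
#'   (normalize first with [normalize_data()] for normalized-scale specs).
#' @param theta Parameter value; required iff the spec uses one.
#' @param family Likelihood family; required with `theta`.
#' @return A single numeric value.
#' @export
compute_discrepancy <- function(spec, x, theta = NULL, family = NULL) {
  stopifnot(inherits(spec, "disc_spec"))
  if (length(x) == 0) stop("empty data", call. = FALSE)
  if (length(x) < 2 &&
      spec$name %in% c("variance", "varc", "skewness", "kurtosis")) {
    stop("'", spec$name, "' needs at least 2 observations", call. = FALSE)
  }
  as.numeric(disc_rows(spec, matrix(x, nrow = 1), theta, family))
}

#' Normalize data via the randomized probability integral transform
#'
#' Maps observations to the standard-normal scale:
#' \eqn{y_i = \Phi^{-1}(F_\theta^{rand}(x_i, u_i))} with the randomized CDF
#' of [cdf_randomized()].  If `x ~ f(. | theta)`, the result is exactly
#' i.i.d. N(0, 1).  CDF values of exactly 0 or 1 are clamped away from the
#' boundary (with a warning) so the quantile stays finite.
#'
#' @param family Likelihood family.
#' @param theta Parameter value (or matrix with one row per observation).
#' @param x Observation vector.
#' @param u Vector of U(0, 1) draws, independent of everything else
#'   (default: freshly drawn).
#' @return Numeric vector of normalized values.
#' @export
normalize_data <- function(family, theta, x, u = stats::runif(length(x))) {
  stopifnot(length(u) == length(x))
  v <- cdf_randomized(family, theta, x, u)
  eps <- .Machine$double.eps
  if (any(v <= 0) || any(v >= 1)) {
    warning("PIT values at the boundary were clamped", call. = FALSE)
    v <- pmin(pmax(v, eps), 1 - eps)
  }
  stats::qnorm(v)
}

.disc_registry <- list(
  mean = list(scales = c("raw", "normalized"), needs_theta = FALSE),
  variance = list(scales = c("raw", "normalized"), needs_theta = FALSE),
  meanc = list(scales = "raw", needs_theta = TRUE),
  varc = list(scales = "raw", needs_theta = TRUE),
  maximum = list(scales = c("raw", "normalized"), needs_theta = FALSE),
  skewness = list(scales = "normalized", needs_theta = FALSE),
  kurtosis = list(scales = "normalized", needs_theta = FALSE),
  za = list(scales = "normalized", needs_theta = FALSE),
  loglik = list(scales = "raw", needs_theta = TRUE)
)
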