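#' Count replicates more extreme than the observed discrepancy
#'
#' Computes the randomized ("ventilated") extremeness count
#' \eqn{a^* = \#\{d_k > d_{obs}\} + u\,\#\{d_k = d_{obs}\}}: ties between
#' observed and replicated discrepancies are allocated to "more extreme"
#' with probability `tie_u`, which makes the resulting p-value exactly
#' uniform even for discrete-valued discrepancies.  Equality is detected
#' within relative tolerance 1e-12 (integer-valued statistics therefore
#' compare exactly).
#'
#' @param d_obs Observed discrepancy; a scalar, or a vector of length `K`
#'   for pairwise engines where the observed value is re-evaluated at each
#'   replicate's parameter draw.
#' @param d_reps Vector of `K` replicated discrepancies.
#' @param tie_u A single U(0, 1) draw used for all ties.
#' @return List with `a_star`, `K`, `n_greater`, `n_equal`.
#' @export
count_extremes <- function(d_obs, d_reps, tie_u) {
  K <- length(d_reps)
  stopifnot(K >= 1, tie_u >= 0, tie_u <= 1,
            length(d_obs) %in% c(1L, K))
  tol <- 1e-12 * pmax(abs(d_obs), abs(d_reps), 1)
  eq <- abs(d_reps - d_obs) <= tol
  gt <- d_reps > d_obs & !eq
  n_greater <- sum(gt)
  n_equal <- sum(eq)
  list(a_star = n_greater + tie_u * n_equal, K = K,
       n_greater = n_greater, n_equal = n_equal)
}

#' Beta-draw Monte Carlo p-value estimator
#'
#' Rather than reporting the raw proportion `a_star / K`, the p-value is a
#' single draw from `Beta(a_star + 1, K - a_star + 1)` — the posterior of
#' the underlying p-value under a uniform prior after observing `a_star`
#' "more extreme" outcomes among `K`.  Pooling such draws over replicated
#' datasets reproduces the distribution of the exact p-value, whereas the
#' raw proportion is visibly discretized at small `K`, especially in the
#' tails.
#'
#' @param a_star Randomized extremeness count in `[0, K]`.
#' @param K Number of Monte Carlo replicates.
#' @return One draw strictly inside (0, 1).
#' @export
beta_draw_pvalue <- function(a_star, K) {
  stopifnot(a_star >= 0, a_star <= K)
  p <- stats::rbeta(1, a_star + 1, K - a_star + 1)
  # guard against numerically degenerate draws at huge shape imbalance
  min(max(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

engine_names <- c("spp", "nspp", "ppost", "plugml", "halfml", "prior",
                  "freqspp")

#' Goodness-of-fit p-values for conjugate Bayesian models
#'
#' Computes one internal goodness-of-fit p-value for observations `x` under
#' the statistical model `model`, using `K` Monte Carlo replicates and the
#' randomized-tie beta-draw estimator.  Engines differ in where the
#' parameter value(s) behind the reference replicates come from:
#'
#' * `spp` — *sampled posterior p-value*: a **single** draw
#'   \eqn{\tilde\theta} from the posterior given `x`; all replicates from
#'   \eqn{f(\cdot\mid\tilde\theta)}; the discrepancy is evaluated at
#'   \eqn{\tilde\theta}.  Exactly uniform when the statistical prior equals
#'   the data-generating prior, for every discrepancy function.
#' * `nspp` — SPP on normalized data: `x` is passed through the randomized
#'   PIT and the standard-normal quantile at \eqn{\tilde\theta}; replicates
#'   are then i.i.d. standard normal.  Pivotal, hence uniform at any `n`
#'   under matched priors.
#' * `ppost` — posterior predictive: a fresh posterior draw \eqn{\theta_k}
#'   per replicate; `d(X_k, theta_k)` is compared with `d(x, theta_k)`
#'   pairwise.  Conservative for parameter-dependent statistics.
#' * `plugml` — parametric bootstrap at the full-data MLE.
#' * `halfml` — plug-in at the MLE of a uniformly random half of the data
#'   (size `floor(n/2)`, without replacement); classically the statistic is
#'   evaluated on data normalized with the half-sample estimate, but raw
#'   test statistics are also accepted.
#' * `prior` — prior predictive: \eqn{\theta_k} from the prior, pairwise
#'   comparison as `ppost`.
#' * `freqspp` — frequentist SPP (Poisson only): \eqn{\tilde\theta} drawn on
#'   the log scale from the asymptotic normal law of the GLM estimate, see
#'   [freq_theta_draw()].
#'
#' @param x Numeric vector of i.i.d. observations (raw scale).
#' @param model A `gof_model`: the statistical model (likelihood + prior).
#' @param engine One of `spp`, `nspp`, `ppost`, `plugml`, `halfml`,
#'   `prior`, `freqspp`.
#' @param disc A [discrepancy_spec()] or a registry name.  Normalized-scale
#'   specs are required for `nspp` and are the default for `halfml`;
#'   pairwise and plug-in engines accept either scale.
#' @param K Number of Monte Carlo replicates (default 5000).
#' @param seed Optional integer seed fixing all randomness of this call.
#' @return A `gof_pvalue` object; see [tidy.gof_pvalue()].
#' @examples
#' x <- sample_data("poisson", c(lambda = 1), 50)
#' gof_pvalue(x, poisson_model(1, 1), "spp", "variance", K = 500, seed = 1)
#' @export
gof_pvalue <- function(x, model, engine = "spp", disc = "mean", K = 5000,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- engine_pvalues(x, model, engine, list(disc), K)[[1]]
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  res
}

as_disc_spec <- function(disc, engine) {
  if (inherits(disc, "disc_spec")) return(disc)
  default_scale <- if (engine %in% c("nspp", "halfml")) "normalized" else NULL
  name <- match.arg(disc, names(.disc_registry))
  if (!is.null(default_scale) &&
      default_scale %in% .disc_registry[[name]]$scales) {
    discrepancy_spec(name, default_scale)
  } else {
    discrepancy_spec(name)
  }
}

# Core engine: evaluates a list of discrepancy specs on SHARED parameter
# draws and replicate matrices (one raw and/or one normalized replicate set
# per call), with an independent tie-ventilation uniform and beta draw per
# spec.  Returns a list of gof_pvalue objects.
engine_pvalues <- function(x, model, engine, discs, K, u_vec = NULL,
                           theta_fixed = NULL, tie_us = NULL) {
  engine <- match.arg(engine, engine_names)
  stopifnot(inherits(model, "gof_model"), K >= 1)
  family <- model$family
  check_data(family, x)
  specs <- lapply(discs, as_disc_spec, engine = engine)
  if (engine == "nspp" &&
      any(vapply(specs, function(s) s$input_scale, "") != "normalized")) {
    stop("engine 'nspp' requires normalized-scale discrepancies",
         call. = FALSE)
  }
  n <- length(x)
  scales <- vapply(specs, function(s) s$input_scale, "")
  if (is.null(tie_us)) tie_us <- stats::runif(length(specs))
  need_norm <- any(scales == "normalized")
  if (need_norm && is.null(u_vec)) u_vec <- stats::runif(n)

  if (engine %in% c("ppost", "prior")) {
    if (is_dirac(model)) {
      stop("engine '", engine, "' needs a proper (non-Dirac) prior",
           call. = FALSE)
    }
    src <- if (engine == "ppost") posterior_update(model, x) else model
    Theta <- sample_theta(src, K)
    if (K == 1) {
      Theta <- matrix(Theta, nrow = 1, dimnames = list(NULL, names(Theta)))
    }
    theta_used <- NULL
    if (need_norm) {
      # pairwise: the observed data are re-normalized at each replicate's
      # parameter draw, the replicates themselves (model draws normalized
      # at their own parameter) are exactly standard normal
      Yobs <- normalize_rows(family, Theta, x, u_vec)
      Yrep <- matrix(stats::rnorm(K * n), K, n)
    }
    if (any(scales == "raw")) {
      Xrep <- sample_data_matrix(family, Theta, K, n)
      Xobs <- matrix(rep(x, each = K), nrow = K)
    }
    d_pairs <- lapply(specs, function(s) {
      if (s$input_scale == "normalized") {
        list(obs = disc_rows(s, Yobs), reps = disc_rows(s, Yrep))
      } else {
        list(obs = disc_rows(s, Xobs, Theta, family),
             reps = disc_rows(s, Xrep, Theta, family))
      }
    })
  } else {
    theta <- if (!is.null(theta_fixed)) theta_fixed else switch(engine,
      spp = , nspp = {
        if (is_dirac(model)) {
          stop("engine '", engine, "' needs a proper (non-Dirac) prior",
               call. = FALSE)
        }
        sample_theta(posterior_update(model, x))
      },
      plugml = {
        th <- mle(family, x)
        if (attr(th, "boundary")) {
          stop("boundary MLE (degenerate plug-in model); ",
               "consider a Bayesian engine such as 'spp'", call. = FALSE)
        }
        th
      },
      halfml = {
        th <- mle(family, x, half_sample_indices(n))
        if (attr(th, "boundary")) {
          stop("boundary half-sample MLE; ",
               "consider a Bayesian engine such as 'spp'", call. = FALSE)
        }
        th
      },
      freqspp = freq_theta_draw(family, x)
    )
    theta_used <- theta
    if (need_norm) {
      y <- normalize_data(family, theta, x, u_vec)
      Yrep <- matrix(stats::rnorm(K * n), K, n)
    }
    if (any(scales == "raw")) {
      Xrep <- sample_data_matrix(family, theta, K, n)
    }
    d_pairs <- lapply(specs, function(s) {
      if (s$input_scale == "normalized") {
        list(obs = disc_rows(s, matrix(y, nrow = 1)),
             reps = disc_rows(s, Yrep))
      } else {
        list(obs = disc_rows(s, matrix(x, nrow = 1), theta, family),
             reps = disc_rows(s, Xrep, theta, family))
      }
    })
  }

  purrr::pmap(list(specs, d_pairs, tie_us), function(s, d, tu) {
    ce <- count_extremes(d$obs, d$reps, tu)
    structure(list(p = beta_draw_pvalue(ce$a_star, K), engine = engine,
                   disc = s$name, input_scale = s$input_scale, n = n, K = K,
                   n_greater = ce$n_greater, n_equal = ce$n_equal,
                   a_star = ce$a_star, theta_used = theta_used,
                   tie_u = tu, seed = NA_integer_),
              class = "gof_pvalue")
  })
}

# Row-wise randomized-PIT normalization: row k of the result is x normalized
# with parameter row Theta[k, ], sharing one u vector across rows.
normalize_rows <- function(family, Theta, x, u_vec) {
  K <- nrow(Theta)
  X <- matrix(rep(x, each = K), nrow = K)
  U <- matrix(rep(u_vec, each = K), nrow = K)
  th1 <- Theta[, 1]
  V <- switch(family,
    poisson = stats::ppois(X - 1, th1) + U * stats::dpois(X, th1),
    bernoulli = {
      lower <- ifelse(X >= 1, 1 - th1, 0)
      atom <- ifelse(X >= 1, th1, 1 - th1)
      lower + U * atom
    },
    normal = stats::pnorm(X, th1, sqrt(Theta[, 2]))
  )
  eps <- .Machine$double.eps
  stats::qnorm(matrix(pmin(pmax(V, eps), 1 - eps), nrow = K))
}

#' @export
print.gof_pvalue <- function(x, ...) {
  cat(sprintf(
    "<gof_pvalue> p = %.4f  [engine %s, %s on %s data, n = %d, K = %d]\n",
    x$p, x$engine, x$disc, x$input_scale, x$n, x$K))
  cat(sprintf("  a* = %.2f of K (greater %d, ties %d, tie u = %.3f)\n",
              x$a_star, x$n_greater, x$n_equal, x$tie_u))
  invisible(x)
}

#' Tidy a goodness-of-fit p-value
#'
#' @param x A `gof_pvalue` object.
#' @param ... Unused.
#' @return A one-row tibble with the p-value, engine, discrepancy, Monte
#'   Carlo counts and the sampled parameter value (as a list column).
#' @export
tidy.gof_pvalue <- function(x, ...) {
  tibble::tibble(
    p = x$p, engine = x$engine, disc = x$disc, input_scale = x$input_scale,
    n = x$n, K = x$K, n_greater = x$n_greater, n_equal = x$n_equal,
    a_star = x$a_star, tie_u = x$tie_u, seed = x$seed,
    theta_used = list(x$theta_used)
  )
}

#' @rdname tidy.gof_pvalue
#' @export
glance.gof_pvalue <- function(x, ...) {
  tibble::tibble(p = x$p, engine = x$engine, disc = x$disc, n = x$n, K = x$K)
}

#' Multi-draw SPP quantile band
#'
#' A single SPP depends on one posterior draw, so repeating the analysis can
#' give a different p-value.  This computes `M` SPPs on the same data —
#' sharing one normalization uniform vector across the posterior draws, so
#' different analysts starting from the same `u` get comparable results —
#' and returns their empirical `q`-quantile together with the whole vector.
#'
#' @inheritParams gof_pvalue
#' @param M Number of independent posterior draws (>= 2).
#' @param q Quantile to report (default 0.5, the median SPP).
#' @return List with `p_q` (the quantile) and `pvals` (length `M`).
#' @export
spp_quantile_band <- function(x, model, disc = "mean", K = 5000, M = 20,
                              q = 0.5, seed = NULL) {
  stopifnot(M >= 2, q >= 0, q <= 1)
  if (!is.null(seed)) set.seed(seed)
  u_vec <- stats::runif(length(x))
  pvals <- vapply(seq_len(M), function(i) {
    engine_pvalues(x, model, "spp", list(disc), K, u_vec = u_vec)[[1]]$p
  }, numeric(1))
  list(p_q = as.numeric(stats::quantile(pvals, q)), pvals = pvals)
}
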