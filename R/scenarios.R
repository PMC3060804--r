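#' Default simulation configuration
#'
#' The calibration study never reads external data: every dataset is drawn
#' from a *probabilistic* model (likelihood + generating prior) and analysed
#' under a *statistical* model (same likelihood, possibly different prior).
#' This returns the default configuration describing those laws; any element
#' can be overridden via `...` or through the `config` argument of the
#' simulation functions.
#'
#' Defaults (all on the generating side, per dataset):
#' * Poisson: Gamma prior with mean 1 and variance `v ~ LogNormal(0, 1)`.
#' * Bernoulli: Beta prior with mean 0.4 and concentration
#'   `s ~ LogNormal(log 5, 0.5)`.
#' * Normal: normal–inverse-gamma with `mu0 = 0`, `a0 = 3`, `b0 = 2`
#'   (prior mean of `sigma2` equal to 1) and `kappa0 = 1/v`,
#'   `v ~ LogNormal(0, 1)`.
#' * Statistical-prior sharpness multiplier `mu_sigma0 ~ LogNormal(0, 1)`
#'   (scenarios 2–3) and off-centering factor `theta0 ~ LogNormal(0, 0.5)`
#'   (scenario 3).
#' * Sample size: with probability 0.7 uniform on \[20, 200\] rounded to the
#'   nearest ten, otherwise uniform on (200, 1000\] rounded to the nearest
#'   hundred (`n_law = "default"`), or any fixed set of sizes.
#' * Power study (`power_poisson_mean = 2.5`): the Poisson rate whose
#'   moment-matched, bounded beta-binomial alternative the power study
#'   detects; large enough that truncation at the support maximum is a real
#'   departure, yet below 3 so support maximum 4 stays feasible.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A named list.
#' @export
scenario_config <- function(...) {
  cfg <- list(
    poisson_prior_mean = 1,
    poisson_prior_var_meanlog = 0, poisson_prior_var_sdlog = 1,
    bernoulli_prior_mean = 0.4,
    bernoulli_conc_meanlog = log(5), bernoulli_conc_sdlog = 0.5,
    normal_mu0 = 0, normal_a0 = 3, normal_b0 = 2,
    normal_mu_var_meanlog = 0, normal_mu_var_sdlog = 1,
    mu_sigma0_meanlog = 0, mu_sigma0_sdlog = 1,
    theta0_meanlog = 0, theta0_sdlog = 0.5,
    power_poisson_mean = 2.5,
    n_law = "default"
  )
  utils::modifyList(cfg, list(...))
}

#' Draw one dataset size
#'
#' With probability 0.7 a size uniform on \[20, 200\] rounded to the nearest
#' ten; otherwise uniform on (200, 1000\] rounded to the nearest hundred.
#'
#' @return An integer in `{20, 30, ..., 200, 300, ..., 1000}`.
#' @export
draw_sample_size <- function() {
  if (stats::runif(1) < 0.7) {
    as.integer(round(stats::runif(1, 20, 200) / 10) * 10)
  } else {
    as.integer(round(stats::runif(1, 200, 1000) / 100) * 100)
  }
}

draw_n <- function(n_law) {
  if (identical(n_law, "default")) return(draw_sample_size())
  if (is.numeric(n_law)) {
    return(as.integer(if (length(n_law) == 1) n_law else sample(n_law, 1)))
  }
  stop("invalid n_law", call. = FALSE)
}

# Scenario-1 generating prior for one dataset (hyperparameters vary between
# datasets through the dispersion laws in `cfg`).
draw_base_prior <- function(family, cfg) {
  switch(family,
    poisson = {
      v <- stats::rlnorm(1, cfg$poisson_prior_var_meanlog,
                         cfg$poisson_prior_var_sdlog)
      m <- cfg$poisson_prior_mean
      poisson_model(shape = m^2 / v, rate = m / v)
    },
    bernoulli = {
      s <- stats::rlnorm(1, cfg$bernoulli_conc_meanlog,
                         cfg$bernoulli_conc_sdlog)
      m <- cfg$bernoulli_prior_mean
      bernoulli_model(m * s, (1 - m) * s)
    },
    normal = {
      v <- stats::rlnorm(1, cfg$normal_mu_var_meanlog,
                         cfg$normal_mu_var_sdlog)
      # E[sigma2] = b0/(a0-1); kappa0 chosen so the prior variance of the
      # mean, E[sigma2]/kappa0, equals v
      normal_model(cfg$normal_mu0,
                   kappa0 = (cfg$normal_b0 / (cfg$normal_a0 - 1)) / v,
                   a0 = cfg$normal_a0, b0 = cfg$normal_b0)
    }
  )
}

prior_mean_theta <- function(model) {
  p <- model$prior
  switch(model$family,
    poisson = c(lambda = p$shape / p$rate),
    bernoulli = c(p = p$shape1 / (p$shape1 + p$shape2)),
    normal = c(mu = p$mu0, sigma2 = p$b0 / (p$a0 - 1))
  )
}

# Rescale a prior's dispersion by mu_sigma0 (variance x mu_sigma0^2) at
# fixed center, then multiply the center by theta0 on the natural scale.
perturb_prior <- function(model, mu_sigma0, theta0) {
  p <- model$prior
  switch(model$family,
    poisson = {
      a <- p$shape / mu_sigma0^2
      b <- p$rate / mu_sigma0^2
      poisson_model(a, b / theta0)
    },
    bernoulli = {
      a <- p$shape1 / mu_sigma0^2
      b <- p$shape2 / mu_sigma0^2
      m <- stats::plogis(stats::qlogis(a / (a + b)) + log(theta0))
      s <- a + b
      bernoulli_model(m * s, (1 - m) * s)
    },
    normal = {
      kappa0 <- p$kappa0 / mu_sigma0^2
      sd_mu <- sqrt(p$b0 / (p$a0 - 1) / kappa0)
      normal_model(p$mu0 + log(theta0) * sd_mu, kappa0, p$a0, p$b0)
    }
  )
}

#' Generate one probabilistic/statistical model pair and dataset
#'
#' Implements the four calibration scenarios:
#'
#' 1. Statistical model identical to the probabilistic model (matched
#'    priors; hyperparameters may vary between datasets but are shared).
#' 2. Same prior center, statistical-prior variance multiplied by
#'    `mu_sigma0^2` with `mu_sigma0 ~ LogNormal(0, 1)` — values above 1
#'    make the analysis prior *less* informative than the generating one.
#' 3. As scenario 2, plus a multiplicative off-centering `theta0
#'    ~ LogNormal(0, 0.5)` of the statistical-prior center (Poisson: prior
#'    mean times `theta0`; Bernoulli: log-odds shifted by `log theta0`;
#'    Normal: center shifted by `log(theta0)` prior-sd units).
#' 4. Probabilistic prior degenerate (Dirac) at the mean of the scenario-1
#'    statistical prior; analysis prior unchanged.
#'
#' The dataset is then drawn by sampling `theta_true` from the probabilistic
#' prior and `n` observations from the likelihood.
#'
#' @param scenario Integer 1–4.
#' @param family `"poisson"`, `"bernoulli"` or `"normal"`.
#' @param config A [scenario_config()] list.
#' @return A `scenario_pair` list: `scenario`, `family`, `probabilistic` and
#'   `statistical` (`gof_model`s), `mu_sigma0`, `theta0`, `n`, `theta_true`,
#'   `x`.
#' @export
make_scenario_pair <- function(scenario, family = "poisson",
                               config = scenario_config()) {
  stopifnot(scenario %in% 1:4)
  family <- match.arg(family, c("poisson", "bernoulli", "normal"))
  cfg <- utils::modifyList(scenario_config(), config)
  base <- draw_base_prior(family, cfg)
  mu_sigma0 <- 1
  theta0 <- 1
  if (scenario %in% 2:3) {
    mu_sigma0 <- stats::rlnorm(1, cfg$mu_sigma0_meanlog, cfg$mu_sigma0_sdlog)
  }
  if (scenario == 3) {
    theta0 <- stats::rlnorm(1, cfg$theta0_meanlog, cfg$theta0_sdlog)
  }
  probabilistic <- base
  statistical <- if (scenario %in% 2:3) {
    perturb_prior(base, mu_sigma0, theta0)
  } else {
    base
  }
  if (scenario == 4) {
    probabilistic <- dirac_model(family, prior_mean_theta(base))
  }
  n <- draw_n(cfg$n_law)
  theta_true <- sample_theta(probabilistic)
  x <- sample_data(family, theta_true, n)
  structure(list(scenario = scenario, family = family,
                 probabilistic = probabilistic, statistical = statistical,
                 mu_sigma0 = mu_sigma0, theta0 = theta0, n = n,
                 theta_true = theta_true, x = x),
            class = "scenario_pair")
}

#' Moment-matched beta-binomial (Polya) parameters
#'
#' Solves `mean = m a/(a+b)` and
#' `var = m p (1-p) (a+b+m)/(a+b+1)` (with `p = mean/m`) for the
#' beta-binomial shape parameters, so the bounded alternative has exactly
#' the mean and variance of a target (e.g. Poisson) distribution.  The
#' target is feasible only if the variance strictly exceeds the binomial
#' variance `m p (1-p)` and stays below `m^2 p (1-p)`.
#'
#' @param m Support maximum (observations lie in `{0, ..., m}`).
#' @param mean,var Target moments, `0 < mean < m`.
#' @return A `polya_params` list with `m`, `alpha`, `beta`.
#' @examples
#' polya_moment_match(5, 1, 1)  # alpha = 3, beta = 12
#' @export
polya_moment_match <- function(m, mean, var) {
  stopifnot(m >= 1, mean > 0, mean < m, var > 0)
  p <- mean / m
  r <- var / (m * p * (1 - p))
  if (r <= 1 || r >= m) {
    stop("infeasible beta-binomial moments: need m p (1-p) < var < m^2 p (1-p)",
         call. = FALSE)
  }
  s <- (m - r) / (r - 1)
  structure(list(m = as.integer(m), alpha = p * s, beta = (1 - p) * s),
            class = "polya_params")
}

#' Sample from a beta-binomial (Polya) distribution
#'
#' One beta draw per observation followed by a binomial draw, giving i.i.d.
#' beta-binomial values on `{0, ..., m}`.
#'
#' @param params A [polya_moment_match()] result.
#' @param n Number of observations.
#' @return Integer vector of length `n`.
#' @export
sample_polya <- function(params, n) {
  stopifnot(inherits(params, "polya_params"), n >= 1)
  stats::rbinom(n, params$m, stats::rbeta(n, params$alpha, params$beta))
}

#' Run a batch of simulated goodness-of-fit analyses
#'
#' Generates `reps` datasets under a scenario (or the Polya alternative) and
#' computes a p-value for every engine × discrepancy combination on each
#' dataset.  Datasets are shared across engines and discrepancies within a
#' replicate; each (replicate, engine) pair consumes an independent child
#' random stream derived from `seed`, so adding engines or discrepancies
#' never perturbs the others.  Engines that fail on a dataset (e.g. a
#' boundary MLE for `plugml`/`halfml`) yield `NA` p-values.
#'
#' When `scenario = "polya"`, data are drawn from a beta-binomial with
#' moments matched to the power-study Poisson rate (`power_poisson_mean` in
#' [scenario_config()]; support maximum `polya_m`, drawn per dataset when
#' several values are given) and analysed under the corresponding Poisson
#' statistical model — the power study design.
#'
#' @param scenario 1–4, or `"polya"` for the power alternative.
#' @param family Likelihood family (ignored for `"polya"`, which is
#'   Poisson).
#' @param engines Character vector of engine names.
#' @param discs List of discrepancy names or [discrepancy_spec()]s.
#' @param reps Number of simulated datasets.
#' @param K Monte Carlo replicates per p-value.
#' @param seed Master seed (mandatory: the batch is fully reproducible).
#' @param config [scenario_config()] overrides, e.g. `list(n_law = 20:50)`.
#' @param polya_m Support maxima for the Polya alternative (default
#'   `c(4, 5)`, one value sampled per dataset).
#' @return A tibble with one row per (replicate, engine, discrepancy):
#'   columns `rep`, `scenario`, `family`, `engine`, `disc`, `input_scale`,
#'   `p`, `n`, `mu_sigma0`, `theta0`, `seed`.
#' @export
run_batch <- function(scenario, family = "poisson", engines = "spp",
                      discs = list("mean"), reps = 100, K = 1000,
                      seed = 1, config = list(), polya_m = c(4, 5)) {
  stopifnot(reps >= 1, !is.null(seed))
  if (!is.list(discs)) discs <- as.list(discs)
  engines <- vapply(engines, match.arg, "", choices = engine_names,
                    USE.NAMES = FALSE)
  cfg <- utils::modifyList(scenario_config(), config)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  rows <- purrr::map(seq_len(reps), function(i) {
    set.seed(rep_seeds[i])
    if (identical(scenario, "polya")) {
      pcfg <- cfg
      pcfg$poisson_prior_mean <- cfg$power_poisson_mean
      base <- draw_base_prior("poisson", pcfg)
      lambda_star <- prior_mean_theta(base)[["lambda"]]
      m <- if (length(polya_m) > 1) sample(polya_m, 1) else polya_m
      pp <- polya_moment_match(m, lambda_star, lambda_star)
      n <- draw_n(cfg$n_law)
      pair <- list(scenario = "polya", family = "poisson",
                   statistical = base, mu_sigma0 = 1, theta0 = 1, n = n,
                   x = sample_polya(pp, n))
    } else {
      pair <- make_scenario_pair(scenario, family, cfg)
    }
    eng_seeds <- sample.int(.Machine$integer.max - 1L, length(engines))
    purrr::map2(engines, eng_seeds, function(eng, es) {
      set.seed(es)
      ok <- tryCatch(
        engine_pvalues(pair$x, pair$statistical, eng, discs, K),
        error = function(e) NULL
      )
      if (is.null(ok)) {
        tibble::tibble(
          engine = eng,
          disc = vapply(discs, function(d)
            if (inherits(d, "disc_spec")) d$name else d, ""),
          input_scale = NA_character_, p = NA_real_
        )
      } else {
        tibble::tibble(
          engine = eng,
          disc = vapply(ok, function(r) r$disc, ""),
          input_scale = vapply(ok, function(r) r$input_scale, ""),
          p = vapply(ok, function(r) r$p, numeric(1))
        )
      }
    }) |>
      purrr::list_rbind() |>
      dplyr::mutate(rep = i, scenario = as.character(pair$scenario),
                    family = pair$family, n = pair$n,
                    mu_sigma0 = pair$mu_sigma0, theta0 = pair$theta0,
                    seed = rep_seeds[i])
  })
  purrr::list_rbind(rows) |>
    dplyr::select(dplyr::all_of(c("rep", "scenario", "family", "engine",
                                  "disc", "input_scale", "p", "n",
                                  "mu_sigma0", "theta0", "seed")))
}
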