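test_that("conjugate posterior updates match the closed forms", {
  m <- posterior_update(poisson_model(2, 1), c(1, 2))
  expect_equal(unlist(m$prior), c(shape = 5, rate = 3))

  m <- posterior_update(bernoulli_model(1, 1), c(1, 0, 1))
  expect_equal(unlist(m$prior), c(shape1 = 3, shape2 = 2))

  m <- posterior_update(poisson_model(0.5, 2), c(0, 0, 0))
  expect_equal(unlist(m$prior), c(shape = 0.5, rate = 5))

  # normal-inverse-gamma update against the textbook formulas
  x <- c(-0.3, 1.2, 0.7, 2.1)
  m <- posterior_update(normal_model(0, 2, 3, 2), x)
  n <- length(x); xbar <- mean(x)
  expect_equal(m$prior$kappa0, 2 + n)
  expect_equal(m$prior$mu0, (2 * 0 + n * xbar) / (2 + n))
  expect_equal(m$prior$a0, 3 + n / 2)
  expect_equal(m$prior$b0,
               2 + 0.5 * sum((x - xbar)^2) + 2 * n * xbar^2 / (2 * (2 + n)))
})

test_that("posterior updates are sequentially consistent and close over the family", {
  set.seed(41)
  for (family in families) {
    model <- example_model(family)
    x1 <- sample_data(family, example_theta(family), 7)
    x2 <- sample_data(family, example_theta(family), 5)
    seq_up <- posterior_update(posterior_update(model, x1), x2)
    one_up <- posterior_update(model, c(x1, x2))
    expect_equal(seq_up$prior, one_up$prior)
    expect_identical(seq_up$family, family)
    expect_equal(posterior_update(model, numeric(0))$prior, model$prior)
  }
  expect_error(posterior_update(dirac_model("poisson", c(lambda = 2)), 1:3),
               "Dirac")
  expect_error(posterior_update(poisson_model(1, 1), c(-1, 2)), "nonnegative")
})

test_that("sample_theta draws from the right law", {
  expect_equal(sample_theta(dirac_model("poisson", c(lambda = 2))),
               c(lambda = 2))
  set.seed(7)
  th <- sample_theta(poisson_model(3, 2), 1e5)
  expect_equal(mean(th), 3 / 2,
               tolerance = 5 * sqrt(3 / 4) / sqrt(1e5) / (3 / 2))
  th <- sample_theta(bernoulli_model(3, 2), 1e4)
  expect_true(all(th > 0 & th < 1))
  th <- sample_theta(normal_model(1, 4, 3, 2), 1e5)
  # E[sigma2] = b0/(a0-1) = 1; E[mu] = mu0
  expect_equal(mean(th[, "sigma2"]), 1, tolerance = 0.05)
  expect_equal(mean(th[, "mu"]), 1, tolerance = 0.05)
})

test_that("sample_data respects supports and degenerate parameters", {
  expect_error(sample_data("poisson", c(lambda = 0), 5), "invalid parameter")
  expect_equal(sample_data("bernoulli", c(p = 1), 5), rep(1L, 5))
  set.seed(8)
  x <- sample_data("normal", c(mu = 0, sigma2 = 1), 1e5)
  expect_lt(abs(mean(x)), 3 / sqrt(1e5))
})

test_that("MLEs are subset means/proportions with boundary flags", {
  expect_equal(mle("poisson", c(1, 2, 3)), c(lambda = 2), ignore_attr = TRUE)
  expect_equal(mle("poisson", c(1, 3, 2, 4), subset = c(1, 4)),
               c(lambda = 2.5), ignore_attr = TRUE)
  expect_equal(mle("bernoulli", c(1, 1, 0, 0)), c(p = 0.5),
               ignore_attr = TRUE)
  expect_false(attr(mle("poisson", c(1, 2, 3)), "boundary"))
  expect_true(attr(mle("poisson", c(0, 0)), "boundary"))
  expect_true(attr(mle("bernoulli", c(1, 1)), "boundary"))
  # ML variance has denominator m, not m - 1
  est <- mle("normal", c(1, 2, 3, 6))
  expect_equal(est[["sigma2"]], mean((c(1, 2, 3, 6) - 3)^2))
  expect_error(mle("poisson", 1:3, subset = integer(0)), "empty subset")
})

test_that("randomized CDF interpolates discrete atoms and is exact for continuous", {
  expect_equal(cdf_randomized("normal", c(0, 1), 0, u = 0.1), 0.5)
  expect_equal(cdf_randomized("normal", c(0, 1), 0, u = 0.9), 0.5)
  expect_equal(cdf_randomized("poisson", c(lambda = 1), 0, u = 0.5),
               0.5 * exp(-1))
  expect_equal(cdf_randomized("poisson", c(lambda = 1), 0, u = 1), exp(-1))
  # strictly increasing in u on an atom
  u <- seq(0, 1, 0.1)
  v <- cdf_randomized("poisson", c(lambda = 2), 1, u = u)
  expect_true(all(diff(v) > 0))
  v <- cdf_randomized("bernoulli", c(p = 0.3), c(0, 1), u = c(1, 0))
  expect_equal(v, c(0.7, 0.7))
})

test_that("randomized PIT is exactly uniform for every family", {
  set.seed(12)
  n <- 1e5
  for (family in families) {
    theta <- example_theta(family)
    x <- sample_data(family, theta, n)
    v <- cdf_randomized(family, theta, x, u = runif(n))
    # float-precision collisions among 1e5 uniforms trigger the ties warning
    expect_gt(suppressWarnings(stats::ks.test(v, "punif"))$p.value, 0.001)
  }
})

test_that("model moments are the closed forms", {
  expect_equal(model_moments("poisson", c(lambda = 2)),
               c(mean = 2, variance = 2))
  expect_equal(model_moments("bernoulli", c(p = 0.5)),
               c(mean = 0.5, variance = 0.25))
  expect_equal(model_moments("normal", c(mu = 1, sigma2 = 4)),
               c(mean = 1, variance = 4))
})

test_that("frequentist rate draw follows the log-scale GLM law", {
  set.seed(9)
  x <- c(rep(2, 40), rep(3, 20))  # sum 140, mean 140/60
  draws <- replicate(2e4, log(freq_theta_draw("poisson", x)[["lambda"]]))
  se <- 1 / sqrt(sum(x))
  expect_equal(mean(draws), log(mean(x)), tolerance = 4 * se / sqrt(2e4) * 5)
  expect_equal(sd(draws), se, tolerance = 0.05 * se)
  expect_true(all(exp(draws) > 0))
  expect_error(freq_theta_draw("poisson", c(0, 0)), "boundary")
  expect_error(freq_theta_draw("normal", c(1, 2)), "poisson")
})
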