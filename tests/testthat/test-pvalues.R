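test_that("count_extremes ventilates ties and orders correctly", {
  ce <- count_extremes(1, c(2, 2, 0), tie_u = 0.5)
  expect_equal(ce$a_star, 2)
  ce <- count_extremes(1, c(1, 1), tie_u = 0.5)
  expect_equal(ce$a_star, 1)
  expect_equal(ce$n_equal, 2)
  ce <- count_extremes(5, c(1, 2), tie_u = 0.9)
  expect_equal(ce$a_star, 0)
  # near-equal floats within relative 1e-12 count as ties
  ce <- count_extremes(1, 1 + 1e-14, tie_u = 0.3)
  expect_equal(ce$n_equal, 1)
  # pairwise form: per-replicate observed values
  ce <- count_extremes(c(0, 2, 1), c(1, 1, 1), tie_u = 0.5)
  expect_equal(ce$a_star, 1 + 0.5)
})

test_that("a_star is non-increasing in the observed discrepancy", {
  set.seed(31)
  reps <- rpois(200, 4)
  u <- 0.42
  a <- vapply(sort(unique(c(reps, -1, 100))), function(d)
    count_extremes(d, reps, u)$a_star, numeric(1))
  expect_true(all(diff(a) <= 0))
})

test_that("beta-draw estimator has the posterior-mean calibration", {
  set.seed(32)
  draws <- replicate(2e4, beta_draw_pvalue(50, 100))
  expect_equal(mean(draws), 51 / 102, tolerance = 3 * 0.05 / sqrt(2e4) / 0.5)
  draws <- replicate(200, beta_draw_pvalue(5000, 5000))
  expect_gt(mean(draws), 0.999)
  expect_true(all(draws > 0 & draws < 1))
  # K = 0: no information, a uniform draw
  draws <- replicate(2e3, beta_draw_pvalue(0, 0))
  expect_gt(ks.test(draws, "punif")$p.value, 0.001)
})

test_that("a constant discrepancy makes every replicate tie", {
  set.seed(33)
  x <- sample_data("poisson", c(lambda = 1), 20)
  const <- discrepancy_spec("const", "raw", fn = function(x, theta, family) 1)
  res <- sppgof:::engine_pvalues(x, poisson_model(1, 1), "spp", list(const),
                                 K = 2000, tie_us = 0.3)[[1]]
  expect_equal(res$n_equal, 2000)
  expect_equal(res$a_star, 0.3 * 2000)
  expect_equal(res$p, 0.3, tolerance = 0.05)
})

test_that("all engines return valid results on each family", {
  set.seed(34)
  for (family in families) {
    model <- example_model(family)
    x <- sample_data(family, example_theta(family), 30)
    engines <- c("spp", "nspp", "ppost", "plugml", "halfml", "prior")
    if (family == "poisson") engines <- c(engines, "freqspp")
    for (eng in engines) {
      disc <- if (eng %in% c("nspp", "halfml")) "variance" else "mean"
      res <- gof_pvalue(x, model, eng, disc, K = 200)
      expect_s3_class(res, "gof_pvalue")
      expect_true(res$p > 0 && res$p < 1, info = paste(family, eng))
      expect_true(res$n_greater + res$n_equal <= res$K)
      td <- tidy(res)
      expect_equal(nrow(td), 1)
      expect_equal(td$p, res$p)
    }
  }
})

test_that("engine preconditions are enforced", {
  x <- c(0, 0, 0, 0)
  expect_error(gof_pvalue(x, dirac_model("poisson", c(lambda = 1)), "spp"),
               "Dirac")
  expect_error(gof_pvalue(x, poisson_model(1, 1), "plugml", "mean"),
               "boundary")
  expect_error(gof_pvalue(x, poisson_model(1, 1), "halfml", "mean"),
               "boundary")
  expect_error(
    gof_pvalue(1:3, poisson_model(1, 1), "nspp",
               discrepancy_spec("mean", "raw")),
    "normalized")
  expect_error(gof_pvalue(c(0, 1), bernoulli_model(1, 1), "freqspp"),
               "poisson")
})

test_that("results are reproducible given a seed", {
  x <- sample_data("poisson", c(lambda = 2), 25)
  r1 <- gof_pvalue(x, poisson_model(2, 1), "spp", "variance", K = 300,
                   seed = 99)
  r2 <- gof_pvalue(x, poisson_model(2, 1), "spp", "variance", K = 300,
                   seed = 99)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$theta_used, r2$theta_used)
  expect_identical(r1$seed, 99L)
})

test_that("SPP is uniform under matched priors for raw and discrete statistics", {
  # Lemma behaviour at small n: Bernoulli, matched Beta(2,3) prior, n = 5
  set.seed(35)
  model <- bernoulli_model(2, 3)
  pvals <- replicate(2000, {
    theta <- sample_theta(model)
    x <- sample_data("bernoulli", theta, 5)
    sppgof:::engine_pvalues(x, model, "spp", list("mean"), K = 150)[[1]]$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("NSPP is pivotal (uniform) at n = 20 under matched priors", {
  set.seed(36)
  model <- normal_model(0, 1, 3, 2)
  pvals <- replicate(2000, {
    theta <- sample_theta(model)
    x <- sample_data("normal", theta, 20)
    sppgof:::engine_pvalues(x, model, "nspp",
                            list(discrepancy_spec("variance", "normalized")),
                            K = 150)[[1]]$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("quantile band returns the requested quantile of its own draws", {
  set.seed(37)
  x <- sample_data("poisson", c(lambda = 1), 40)
  qb <- spp_quantile_band(x, poisson_model(1, 1), "variance", K = 200,
                          M = 11, q = 0.5, seed = 5)
  expect_length(qb$pvals, 11)
  expect_true(all(qb$pvals > 0 & qb$pvals < 1))
  expect_equal(qb$p_q, median(qb$pvals))
})
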