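# Shared fixtures built in code.

families <- c("poisson", "bernoulli", "normal")

example_model <- function(family) {
  switch(family,
    poisson = poisson_model(2, 2),
    bernoulli = bernoulli_model(2, 3),
    normal = normal_model(0, 1, 3, 2)
  )
}

example_theta <- function(family) {
  switch(family,
    poisson = c(lambda = 1.3),
    bernoulli = c(p = 0.4),
    normal = c(mu = 0.5, sigma2 = 2)
  )
}

# Monte Carlo standard error of a proportion.
prop_se <- function(p, n) sqrt(p * (1 - p) / n)
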