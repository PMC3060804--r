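---
title: "Sampled posterior p-values: models, engines and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampled posterior p-values: models, engines and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Internal goodness-of-fit (GOF) asks whether a fitted Bayesian model is
compatible with the very data used to fit it.  The Fisherian formulation
compares an observed discrepancy $d(\mathbf{x}_{obs}, \theta)$ with the
distribution of $d(\mathbf{X}, \theta)$ when $(\mathbf{X}, \theta)$ are
simulated from a *reference density* attached to the statistical model; a
p-value near either end of $[0,1]$ signals surprise.  Such p-values are only
interpretable if, over hypothetical datasets drawn from the model, they are
(at least asymptotically) uniform — and the most popular choice, the
posterior predictive p-value, is *not*: for statistics whose mean depends on
the parameters it concentrates around $1/2$, sacrificing power.

The **sampled posterior p-value (SPP)** fixes this with a strikingly simple
reference: draw **one** value $\tilde\theta$ from the posterior given
$\mathbf{x}_{obs}$, then simulate all $K$ reference replicates from the
likelihood $f(\cdot \mid \tilde\theta)$ and evaluate the discrepancy at
$\tilde\theta$ throughout:

$$p_{spp} = \Pr\{ d(\mathbf{X}, \tilde\theta) > d(\mathbf{x}_{obs},
\tilde\theta)\} + u \cdot \Pr\{ d(\mathbf{X}, \tilde\theta) =
d(\mathbf{x}_{obs}, \tilde\theta)\}, \qquad u \sim U(0,1).$$

When the analysis prior equals the data-generating prior, the joint law of
$(\mathbf{x}_{obs}, \tilde\theta)$ and of a replicate
$(\mathbf{X}, \tilde\theta)$ is exchangeable, and the randomized ("tie
ventilated") p-value above is **exactly uniform for every discrepancy
function**, discrete-valued ones included.  When the priors differ, the
posterior concentrates on the truth as $n \to \infty$ and uniformity holds
asymptotically.  The normalized variant (NSPP) first maps the data through
the randomized probability integral transform and the standard-normal
quantile at $\tilde\theta$, making any test statistic pivotal — uniform at
*every* finite $n$ under matched priors.

## Model families

Three conjugate families are implemented (`poisson_model()`,
`bernoulli_model()`, `normal_model()`), so posteriors are closed-form and
no MCMC is needed:

* Poisson($\lambda$) with $\lambda \sim$ Gamma(shape $a$, rate $b$);
  posterior Gamma($a + \sum x_i$, $b + n$).
* Bernoulli($p$) with $p \sim$ Beta($a$, $b$); posterior
  Beta($a + \sum x_i$, $b + n - \sum x_i$).
* Normal($\mu, \sigma^2$), both unknown, under the fully conjugate
  normal–inverse-gamma prior $\sigma^2 \sim \mathrm{InvGamma}(a_0, b_0)$,
  $\mu \mid \sigma^2 \sim N(\mu_0, \sigma^2/\kappa_0)$.  A semi-conjugate
  structure with independent priors on $\mu$ and $\sigma^2$ would need
  sampling; the NIG form keeps every update analytic, which is the design
  premise of the whole package.

A `dirac_model()` carries a point mass, used when data are generated from
fixed parameters.  Parameter draws, data simulation, MLEs (with explicit
boundary flags: a Poisson subset mean of 0 or a Bernoulli proportion in
$\{0,1\}$ is returned flagged, because half-sample estimation can
legitimately hit the boundary), model moments and the randomized CDF

$$F^{rand}_\theta(x, u) = F_\theta(x^-) + u\,[F_\theta(x) - F_\theta(x^-)]$$

are shared by every engine.  For discrete families $F_\theta(x^-)$ is the
CDF at the largest support point strictly below $x$ (zero below the
support), so $F^{rand}$ is exactly $U(0,1)$ under the model — the property
the normalization $y_i = \Phi^{-1}(F^{rand}_\theta(x_i, u_i))$ inherits.

## Discrepancy registry

`discrepancy_spec()` names the statistic and the scale it acts on.  On the
raw scale: mean, variance, maximum, centered mean and variance (sample
moment minus the model moment at $\theta$), and the joint log-likelihood.
On the normalized scale: mean, variance, maximum, skewness, kurtosis and
Zhang's likelihood-ratio EDF statistic
$Z_A = -\sum_i [\log U_{(i)}/(n-i+0.5) + \log(1-U_{(i)})/(i-0.5)]$ on the
ascending-sorted uniformized values.  Choices where the convention was
open: the plain `variance` (and `varc`) use denominator $n-1$;
skewness/kurtosis use biased moment estimators and kurtosis is raw, not
excess — for p-values only the induced ordering matters, and these are the
simplest monotone-equivalent forms.  User statistics plug in through the
`fn` argument.

## The seven engines

`gof_pvalue()` computes one p-value from `K` Monte Carlo replicates
(default 5,000).  Single-parameter engines (`spp`, `nspp`, `plugml`,
`halfml`, `freqspp`) draw or estimate one $\theta$ and simulate all
replicates at it; pairwise engines (`ppost`, `prior`) refresh $\theta_k$
per replicate and compare $d(\mathbf{X}_k, \theta_k)$ with
$d(\mathbf{x}_{obs}, \theta_k)$.  Two conventions deserve a note:

* **Ties.**  One uniform `tie_u` per p-value ventilates all ties (not one
  per replicate), matching the single-$u$ randomized p-value definition.
  Equality of discrepancies is declared within a relative tolerance of
  1e-12, which is exact for integer-valued statistics.
* **Normalized statistics under pairwise engines.**  `ppost`/`prior`
  re-normalize the observed data at each replicate's own parameter draw
  (one normalization uniform vector shared across draws), while the
  replicates — model draws normalized at their own parameter — are exactly
  standard normal.  A consequence worth knowing: a statistic that is
  (nearly) invariant to location/scale of the normalized values, such as
  skewness or kurtosis, barely feels the parameter draw, so for such
  statistics the posterior predictive engine loses almost none of its
  power relative to the SPP; the conservativeness gap concentrates on
  statistics like the maximum or $Z_A$ whose normalized-scale distribution
  genuinely shifts with the draw.

The Monte Carlo estimate itself is the **beta-draw estimator**: after
counting $a^* = \#\{d_k > d_{obs}\} + u\,\#\{d_k = d_{obs}\}$, the reported
p-value is one draw from Beta($a^*+1$, $K-a^*+1$) — the posterior of the
underlying p-value under a uniform prior.  Pooled over datasets this
reproduces the exact p-value distribution at any $K$, whereas the naive
proportion $a/K$ is discretized (its pooled CDF has steps of size
$\approx 1/K$), which distorts precisely the tails that calibration
diagnostics examine.  The cost is a small extra randomness per call; `K`
controls it.

Because the SPP depends on one posterior draw, repeated analyses of the
same data can differ.  `spp_quantile_band()` computes $M$ SPPs sharing one
normalization uniform vector and reports an empirical quantile — a
reproducible summary two analysts can agree on if they share the initial
uniforms.

## Simulation design

The scenarios module generates every dataset used in testing; nothing is
downloaded.  A *probabilistic* model (likelihood + generating prior
$\pi_0$) produces data analysed under a *statistical* model (same
likelihood, prior $\pi$):

1. $\pi = \pi_0$ (the exact-uniformity regime);
2. same center, statistical-prior variance multiplied by $\mu_{\sigma_0}^2$
   with $\mu_{\sigma_0} \sim$ LogNormal(0, 1) — values above 1 mean a
   *less* informative analysis prior;
3. additionally an off-centering $\theta_0 \sim$ LogNormal(0, 0.5)
   multiplying the prior center on the natural scale (rate for Poisson,
   odds for Bernoulli, prior-sd units of the location for the normal);
4. $\pi_0$ a point mass at the mean of the scenario-1 statistical prior.

Where the published study left numeric settings unspecified, the defaults
in `scenario_config()` are fixed once: Poisson generating prior of mean 1
with variance $\sim$ LogNormal(0, 1) (a prior typically worth about one
pseudo-observation against sample sizes of 20–1,000, so scenario-1
uniformity is tested across genuinely varied prior strengths); Bernoulli
prior mean 0.4 (off the worst-case maximum-variance point $p = 1/2$) with
concentration $\sim$ LogNormal(log 5, 0.5); normal NIG with $\mu_0 = 0$,
$a_0 = 3$, $b_0 = 2$.  The LogNormal(0, 1) sharpness law populates all four
analysis bins ($0.40$, $1.01$, $2.59$ cut points) and LogNormal(0, 0.5)
does the same for the off-centering bins.  Sample sizes follow a
two-component law: uniform on [20, 200] rounded to tens with probability
0.7, else uniform on (200, 1000] rounded to hundreds.

The power study draws data from a **Polya (beta-binomial)** distribution on
$\{0,\dots,m\}$, $m \in \{4,5\}$, with mean and variance *matched to a
Poisson* by `polya_moment_match()` — a bounded-support alternative that no
first- or second-moment statistic can see.  Its rate is a separate default,
`power_poisson_mean = 2.5`: the alternative must truncate the Poisson's
upper tail for maximum-type statistics to have anything to detect
($\Pr(X > 5) \approx 0.04$ at rate 2.5), and the rate must stay below 3 for
the $m = 4$ moment match to remain feasible.  At rate 1 the alternative is
practically indistinguishable at these sample sizes and the power
comparison degenerates to size; that regime is available by overriding the
config, but it is not an informative default.

`run_batch()` ties it together: one dataset per replicate, shared by every
engine × discrepancy combination (statistics are evaluated on shared
replicate matrices per engine), with per-(replicate, engine) child seeds
derived from the master seed so any subset of the grid is reproducible in
isolation.  Engines that fail on a dataset — a boundary MLE for the
plug-in engines, possible on small half-samples — contribute `NA` rows
rather than aborting the batch, and the diagnostics drop them.

## Diagnostics

`calibrate_pvalues()` reports, per engine × discrepancy × stratum: the KS
distance and asymptotic p-value against $U(0,1)$; the frequencies of
p-values in the 5% and 1% **two-sided extremities** (below level/2 or above
$1 - $ level/2 — both tails are suspect for the registry's statistics, and
symmetry is the natural reading of "extremities" of the unit interval); a
**randomized binomial test** whose ventilation uniform makes its p-value
exactly uniform under the null, so its own stars are calibrated; and a
**band code** classifying the Beta(count+1, N−count+1) posterior of the
underlying tail proportion against negligibility bands — `zero_zero` when
the 95% interval sits inside $\pm 0.01$ of the 5% target, `zero` inside
$\pm 0.02$, `plus`/`plus_plus` and `minus`/`minus_minus` for one-sided
departures, cutoffs divided by 5 at the 1% level.  The cutoff widths are a
package choice (the published interval endpoints are not recoverable) and
reproduce the published codes on the published frequencies.
`render_calibration()` lays the codes out as a sharpness × off-centering
text table; `power_summary()` and `autoplot()` cover the power study.

## What the tests do and do not show

The test-suite problem sizes are scaled down from the full study (which
used $10^5$ datasets and $K = 5{,}000$): batches of 2,000–12,000 datasets
with $K = 1{,}000$ for calibration (and $K = 500$ for the power cells,
where only orderings are compared), which resolve tail frequencies to
about $\pm 0.01$ and
leave the qualitative contrasts (exact uniformity under matched priors,
inflation under sharp or off-centered priors, posterior-predictive
conservativeness, the power ordering) clearly visible.  The generator
emulates i.i.d. conjugate-model data only: no regression structure,
hierarchy, dependence, or non-conjugate priors.  Passing tests therefore
certify the calibration machinery and its finite-sample behaviour in this
conjugate i.i.d. world; they do not certify behaviour under model classes
the generator cannot produce, nor the exact numeric cells of the published
tables, whose prior laws are not recoverable from the text.

## Known limitations

* Conjugacy is assumed throughout; plugging in MCMC posteriors is a
  straightforward extension (the SPP needs only one posterior draw) but is
  out of scope here.
* `freqspp` covers the Poisson family only, mirroring the published
  demonstration; its log-scale normal draw requires $\sum x_i > 0$.
* The partial/conditional predictive p-values and post-processed
  calibrations are deliberately excluded: their computational profile is
  what the SPP is designed to avoid.
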