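---
title: "Modelling athlete performance passports with latent factor regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling athlete performance passports with latent factor regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Anti-doping programmes monitor athletes longitudinally through biological
markers (the Athlete Biological Passport). Competition results themselves
are an untapped signal: a doping regime exists to raise performance, so an
unexpected jump in an athlete's results is grounds for targeted testing.
An *athlete performance passport* needs a model that (i) turns sparse,
irregular within-season results into a smooth individual trajectory with
honest uncertainty, (ii) pools information across hundreds of athletes who
each have only a handful of results, and (iii) links trajectory shape to a
binary outcome — a career doping conviction — so that held-out athletes
can be scored.

`perfpassport` implements such a model for "centimeter–gram–second" sports
and ships a synthetic-data generator emulating an elite shot put season
(352 athletes, 1–27 results each over ~360 days), so that the whole
pipeline is testable without access to any proprietary results database.

## The model

For athlete $i$ with result $y_{ij}$ (meters) at day $t_{ij}$ (counted
from that athlete's own first result, so $t_{i1}=0$):

$$y_{ij} = f_i(t_{ij}) + \epsilon_{ij}, \qquad
  \epsilon_{ij} \sim N(0, \psi^2),$$

$$f_i(t) = b(t)^\top \theta_i, \qquad
  b_1(t) = 1,\;\; b_m(t) = \exp\{-b\,(t-\phi_m)^2\},\; m = 2,\dots,p,$$

$$\theta_i = \Lambda \eta_i + \zeta_i, \quad \zeta_i \sim N_p(0, \Sigma),
  \qquad \Sigma = \mathrm{diag}(\sigma^2_1,\dots,\sigma^2_p),$$

$$\eta_i = \beta^\top x_i + \Delta_i, \quad \Delta_i \sim N_k(0, I),$$

$$P(z_i = 1 \mid \alpha, \gamma, \eta_i) = \Phi(\alpha + \gamma^\top \eta_i).$$

The Gaussian-kernel basis gives locally concentrated flexibility; the
sparse latent factor model on the coefficients reduces each athlete to a
$k$-dimensional summary $\eta_i$ that simultaneously drives the curve and
the probit doping probability (scalar-on-function regression). Static
covariates $x_i = (1,\ \text{male},\ \text{age standardized})$ shift the
factor means. The induced law of each curve is a Gaussian process with

$$E[f_i(t)] = \textstyle\sum_m (\beta^\top x_i)_m \tilde\phi_m(t), \qquad
  \tilde\phi_m(t) = \textstyle\sum_l \lambda_{lm} b_l(t),$$

$$\mathrm{Cov}\{f_i(s), f_i(t)\}
  = \textstyle\sum_m \tilde\phi_m(s)\tilde\phi_m(t)
  + \textstyle\sum_l \sigma^2_l\, b_l(s) b_l(t),$$

both available as `induced_mean_function()` and `induced_covariance()`.

The model is deliberately static in its covariates: age is treated as a
single per-athlete value (at the first event of the season), which is only
coherent within one season. Multi-year careers, aging trajectories and
seasonality are out of scope.

## Inference

All priors are conditionally conjugate, so posterior computation is a
pure Gibbs sampler (compiled, single-threaded, driven by R's RNG so runs
are bit-reproducible under a seed):

* $\theta_i$ — normal full conditional combining the athlete's data with
  the factor-model prior (the prior alone if an athlete has no records);
* $\eta_i$ — normal, combining the $\theta_i$ likelihood, the covariate
  prior, and the probit utility;
* rows of $\Lambda$ — normal, under either the multiplicative gamma
  process (MGP) column-shrinkage prior (default; it prunes unneeded
  basis directions) or plain $N(0,1)$ entries;
* $\sigma^2_l, \psi^2$ — inverse gamma;
* $\beta$ columns — normal;
* probit — Albert–Chib: truncated-normal latent utilities
  $u_i \sim N(\alpha + \gamma^\top\eta_i, 1)$ constrained by $z_i$, then
  $(\alpha,\gamma)$ jointly normal.

Defaults: 10,000 iterations, 5,000 burn-in, thinning 5; a seed is
mandatory. `fit_passport(likelihood = FALSE, response = FALSE)` runs the
same cycle with the data terms removed — a Geweke successive-conditional
chain whose stationary marginals are exactly the priors, which the test
suite exploits as a correctness check on every block.

### Priors and their scales

* $\alpha \sim N(\Phi^{-1}(\pi_0), 1)$ with $\pi_0$ the assumed doping
  prevalence (default 1%): the prior mean is directly elicitable from
  expert belief about how common doping is.
* $\beta, \gamma$ entries $\sim N(0,1)$. Because the model has no global
  mean term, `fit_passport()` centers the results internally (storing the
  offset as `y_center` and restoring it in every curve and prediction
  summary); without centering, a ~17 m shot put level would have to pass
  through coefficients that the unit-normal priors cannot carry.
* $\sigma^2_l \sim \mathrm{IG}(1, 0.02)$, prior median ≈ 0.03 m². The
  $\sigma^2_l$ are *coefficient* variances on the centered meter scale:
  athlete-specific departures from the factor structure are fractions of
  a meter, so their variances are of order $10^{-2}$. A scale appropriate
  for unit-variance data (rates near 0.3) concentrates away from this
  region, inflates $\hat\Sigma$, lets the per-athlete curves over-fit,
  and biases $\hat\psi^2$ downward — visible in simulation as failed
  noise-variance recovery.
* $\psi^2 \sim \mathrm{IG}(1, 0.05)$, prior median ≈ 0.07 m²
  (≈0.27 m noise SD), a realistic competition-to-competition variation;
  with thousands of observations the data dominate this prior anyway.
* MGP: $\lambda_{lm} \sim N(0, (\phi_{lm}\tau_m)^{-1})$,
  $\phi_{lm}\sim\mathrm{Ga}(\nu/2,\nu/2)$ with $\nu=3$,
  $\tau_m = \prod_{h\le m}\delta_h$, $\delta_1\sim\mathrm{Ga}(2,1)$,
  $\delta_{h\ge2}\sim\mathrm{Ga}(3,1)$ — increasing stochastic shrinkage
  of later columns.

### Basis defaults

`default_basis(t_max, p)` spaces $p-1$ kernels equally over
$[0, t_\max]$ and sets the bandwidth by a half-overlap rule
($b = \log 2 / (\Delta/2)^2$, $\Delta$ the spacing), so adjacent kernels
cross at height 1/2 regardless of scale. The package default is $p = 20$
for a 360-day season (~19-day resolution); the factor model's shrinkage
prunes excess elements. $k = 5$ factors by default, fixed rather than
adaptively truncated, keeping the sampler simple and its blocks testable.

### Numerical policy

Every conditional precision matrix is Cholesky-factorized with jitter
escalation on failure ($10^{-8}$ up to $10^{-4}$ times the mean diagonal,
then abort naming the block and iteration). Truncated-normal draws use the
inverse CDF in the central region and an exponential rejection sampler in
far tails (|linear predictor| beyond ~5), so extreme probit means never
produce infinite utilities. Non-finite states abort with the iteration
index and offending block.

## Held-out prediction

`predict_doping()` scores athletes whose doping status is withheld. For
each posterior draw, the athlete's factors are sampled from their exact
conditional given only that athlete's records and covariates — the probit
term is omitted because $z$ is unknown ("cut" prediction; the marginal
over $\theta_i$ is used, so no inner Gibbs is needed) — and
$\Phi(\alpha + \gamma^\top \eta_i)$ is evaluated; the reported score is
the across-draw mean. Athletes with no records fall back to the
covariate-only prior and are flagged. Evaluation helpers implement the
stratified athlete split (round-half-up doped count, preserving the
cohort's class balance: 52 of 352 with 13 doped gives exactly 2 doped
test athletes), Mann–Whitney AUC with ties counted ½, and strict
`score > threshold` classification at the 0.5 "random classification"
cutoff.

## The synthetic cohort

`generate_dataset(sim_config())` draws covariates, doping labels, factors,
coefficients, observation days and noisy results from the generative model
itself, with defaults emulating a 2012-style elite shot put season:

| quantity | default | emulates |
|---|---|---|
| athletes | 352 | cohort size |
| doped fraction | 3.69% (13/352, exact-count mode) | conviction rate |
| results/athlete | 1 + Binomial(26, 8.34/26), support 1–27, mean 9.34 | sampling sparsity |
| season | 360 days, uniform days (clustered mode optional) | irregular calendar |
| ages | 15 + 28·Beta(2,5): range 15–43, mean 23 | age structure |
| male fraction | 175/352 | sex balance |
| level | 17 m + 0.8 m (male) + 0.4 m per age-SD | realistic results |
| athlete level SD | ~0.4 m (covariate-adjusted, via factor 1) | between-athlete spread |
| shape factor | ±0.35 m alternating kernel loadings | within-season movement |
| noise | $\psi^{2*} = 0.25$ (0.5 m SD) | competition variation |
| doped effect | +1.0 m on $f_i$ (constant; optional mid-season ramp) | observed group gap |

Choices the data do not pin down were made once on realism grounds: the
Beta age law, uniform sampling days, and the truth parameters above. The
doped shift acts on the smooth curve (doping changes underlying
performance, not measurement noise); a constant shift is absorbed into the
constant-basis coefficient. Doping labels can alternatively be drawn from
the model's own probit (`doping_mode = "probit"`), with $\gamma^*$ applied
to centered factors so the configured prevalence is preserved.

What the generator does *not* emulate: multi-year careers and aging,
training/periodization structure within a season beyond the smooth factor
shapes, event-level covariates (venue, wind), and the possibility that
"clean" athletes are unconvicted dopers. Tests passing on this cohort
demonstrate internal correctness and statistical power under the stated
conditions — not field performance on real results.

## Study configuration used by the automated checks

The cohort-scale checks (test suite and `scripts/acceptance.R`) fit with
the generator's own 8-element basis, $k = 2$ factors and 3,000 iterations
(1,000 burn-in, thin 4) — a configuration chosen to match the two-factor
generative truth and keep a twenty-replicate recovery study comfortably
inside a desktop run; the Geweke prior-recovery check uses a small cohort
with heavy thinning (every 400th iteration) because the KS test presumes
near-independent draws and the loading/factor pair decorrelates over
hundreds of iterations. Parameter-recovery checks use $n = 200$ athletes; detection checks
use the full 352-athlete shape with a 1.5 m (three noise-SD) shift for
ranking power and the default 1.0 m shift for the group-gap estimate.

## Known limitations

* Detection power at a 3.69% conviction rate is modest: with ~11 doped
  training athletes the probit coefficients are weakly identified, and
  ranking of held-out athletes can be unstable for effect sizes below a
  couple of noise SDs. This mirrors the motivating analysis, where
  prediction quality was driven by correct classification of clean
  athletes.
* Fixed $k$: no adaptive factor truncation; rotational ambiguity of
  $(\Lambda, \eta, \beta, \gamma)$ is harmless for prediction and curves
  (which are rotation-invariant) but makes individual loadings
  uninterpretable.
* The model cannot represent short-range within-season autocorrelation
  beyond what the kernel basis captures; results days apart share only
  the smooth curve.
* Same-day repeat results are treated as independent noisy draws of the
  same curve value.
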