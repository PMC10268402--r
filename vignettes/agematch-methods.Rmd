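---
title: "Methods: spatio-temporal matching of ageing and medical resources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal matching of ageing and medical resources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`agematch` analyses how regional medical resources keep pace with population
ageing. The data model is a panel of areal units (typically the 31
provincial-level regions of a national yearbook panel) observed annually,
with four indicators per region-year: the elderly population ratio EPR (the
share of residents aged 65 and over, in percentage points) and three
medical-resource indicators per 1000 population — health institutions (NHI),
beds in health institutions (NBHI) and health technical personnel (NHTP).
Spatial structure enters through a binary first-order contiguity matrix
$W$ ($W_{ij} = 1$ when regions $i$ and $j$ are adjacent, $0$ otherwise,
zero diagonal). This vignette records the models, the tunable parameters
and every numerically consequential choice.

## Moran-family spatial autocorrelation

The global statistic is computed exactly as written for binary weights,

$$I = \frac{n \sum_i \sum_j W_{ij}(x_i-\bar x)(x_j-\bar x)}
          {S_0 \sum_i (x_i-\bar x)^2},
  \qquad S_0 = \sum_i\sum_j W_{ij},$$

without row-standardising $W$. GeoDa's default row-standardisation is
available behind a flag (`row_standardize = TRUE`) but deliberately off:
the binary form is the one the formulas above define, and the two differ
on irregular lattices. The local statistic uses the population variance
$S^2 = \sum_i (x_i - \bar x)^2 / n$,

$$I_i = \frac{x_i-\bar x}{S^2}\sum_j W_{ij}(x_j-\bar x),$$

which makes the aggregation identity $\sum_i I_i = S_0\, I$ exact, and the
bivariate statistic standardises both variables by their population mean
and standard deviation so that it reduces elementwise to $I_i$ when the
two variables coincide. Both identities are enforced to $10^{-10}$ or
better in the test suite against brute-force double-loop oracles.

Inference is by random permutation (conditional permutation for the local
statistics: region $i$'s own value is held fixed while the other $n-1$
values are shuffled). The pseudo p-value is
$(\#\{|I^{(b)}| \ge |I^{obs}|\} + 1)/(B + 1)$ with $B = 999$ permutations by
default; the one-sided version is reported alongside for directional
alternatives such as positive clustering. Cluster labels (HH, LL, LH, HL)
come from the signs of the deviation and the spatial lag, masked to NS when
the pseudo p exceeds `alpha` (default 0.05, the conventional LISA-map
threshold). Two boundary rules are worth stating explicitly:

* a region whose deviation or lag is *exactly* zero is labelled NS — a tie
  carries no directional evidence (on a 4-chain with values $(1,1,-1,-1)$
  the two middle regions' lags cancel exactly, so they are NS even at
  `alpha = 1`);
* an island region (all-zero row of $W$) is labelled ISOLATE with a local
  statistic of 0 and no p-value, rather than being rejected — national
  provincial maps genuinely contain such units.

## The Bayesian spatio-temporal effects model

Let $\theta_{it}$ be the indicator value of region $i$ in year $t$ divided
by the national baseline of year $t$. The model is additive on the log
scale:

$$\log(\theta_{it}) = \beta_0 + \textstyle\sum_{k} \beta_k x_{kit}
  + \varphi_i + \Phi_t + \delta_{it} + \epsilon_{it}.$$

Choices made where the structure was genuinely open:

* **Likelihood.** Gaussian on $\log\theta_{it}$. The response is a smooth
  positive ratio, not a count, so a log-Gaussian model is the natural
  reading of the equation; no Poisson offset exists for a ratio indicator.
* **National baseline.** The unweighted cross-region mean of the indicator
  in year $t$. A population-weighted mean would need population data the
  panel does not carry; the choice is recorded in the fitted object.
* **Spatial effects.** $\varphi \sim$ proper Leroux conditional
  autoregressive field with precision
  $\tau_\varphi^{-2}\left(\rho\,(D - W) + (1-\rho)\,I\right)$, $\rho$
  estimated by a Metropolis random walk on a uniform$(0,1)$ prior
  (proposal s.d. 0.05, log-determinant evaluated from the precomputed
  eigenvalues of $D-W$). The Leroux family is proper for $\rho < 1$,
  degenerates to iid effects at $\rho = 0$, and is the same family the
  synthetic generator simulates from.
* **Temporal effects.** First-order random walk for $\Phi_t$ (an iid
  option exists); **interaction** $\delta_{it}$ iid normal (or none).
  This is the ANOVA-style decomposition of space, time and their
  interaction.
* **Priors.** Inverse-gamma(1, 0.01) on all variances, normal$(0, 10^5)$
  on $\beta_0$ and $\beta$ — conventional weakly-informative defaults for
  CAR spatio-temporal models.
* **Identifiability.** The intercept, spatial, temporal and interaction
  blocks are only jointly identified up to constants, so within every
  iteration $\varphi$ and $\Phi$ are recentred to sum to zero (means
  absorbed into $\beta_0$) and each year-slice of $\delta$ is recentred
  into $\Phi_t$. Stored draws satisfy these constraints to machine
  precision.
* **Covariate scaling.** Covariates are z-scored internally; the transform
  is stored so that `relative_risk()` reports effects per raw unit (e.g.
  per one additional health technician per 1000 population), as
  $\exp(\text{per}\times\beta_k/\text{sd}_k)$ with a posterior-median
  point and 95% equal-tailed interval.

All Gaussian blocks have conjugate full conditionals and are drawn jointly
per block by Cholesky factorisation of the conditional precision (the
spatial block is $n \times n$, the temporal block $T \times T$ — cheap at
panel scale). MCMC defaults are 20 000 iterations, 5 000 burn-in, thinning
2, one chain, seeded; a 31-region, 10-year fit takes well under a minute.

**Convergence** is assessed by the Geweke diagnostic: $z$ compares the
mean of the first 10% of a chain against the last 50%, with standard
errors from the spectral density at frequency zero (AIC-selected
autoregressive fit, so autocorrelation widens the errors). A zero-variance
chain returns $z = 0$ with a flag rather than NaN. One caveat the package
does not hide: the report monitors nine scalar chains, and since each
$z$ is approximately standard normal for a converged chain, the
probability that *all nine* fall inside $\pm 1.96$ is at most about
$0.95^9 \approx 0.63$ even for perfect mixing. The all-parameter pass flag
is therefore a strict, conservative summary; per-parameter values should
be read individually.

**Simulation-based calibration.** The test suite refits the model on 20
independently generated panels (25 regions $\times$ 10 years, known
effects $\beta = (0, 0.01, 0.04)$ on NHI, NBHI, NHTP) and requires the 95%
credible interval to cover each true coefficient in at least 85% of fits.
These fits use 12 000 iterations with 4 000 burn-in — enough for stable
intervals at this panel size while keeping the whole suite under a few
minutes.

## The indicator of ageing-resources (IAR)

From four response-only fits (EPR and the three resource indicators, one
spatio-temporal model each with identical settings and consecutive seeds),
the year-specific spatial relative level of region $i$ is
$\exp(S_i) = \exp(\varphi_i + \delta_{it})$ (posterior means; `"pooled"`
uses $\varphi_i$ alone). Because of the sum-to-zero centring, the
geometric mean of $\exp(S_i)$ across regions is 1. The construction then
proceeds:

1. matching odds ratios $OR_{MR,i} = \exp(S_i^{MR})/\exp(S_i^{EPR})$ per
   resource indicator;
2. weighted combination
   $IAR_{prior,i} = (1-p-q)\,OR_{NHI} + p\,OR_{NBHI} + q\,OR_{NHTP}$ with
   defaults $p = 1/4$, $q = 1/2$, i.e. effective weights
   $(0.25, 0.25, 0.50)$ — technical personnel, the resource most tightly
   coupled to ageing demand, counts double;
3. standardisation by the cross-region arithmetic mean, so
   $\overline{IAR_{st}} = 1$ exactly, computed *per year* over all regions
   (the plausible alternative — pooling the mean over years — is not
   used);
4. sufficiency: $IAR_{st,i} \ge 1$, boundary inclusive.

The kernel density surface over user-supplied planar coordinates (the
package deliberately handles no geometry) is a weighted product-Gaussian
kernel with Silverman's rule-of-thumb bandwidth per axis when
`bandwidth = "auto"`; the default grid margin of four bandwidths keeps the
Riemann mass on the grid within 2% of the total weight.

## The hybrid forecaster

Holt's linear-trend exponential smoothing,

$$s_i = \alpha x_i + (1-\alpha)(s_{i-1}+t_{i-1}), \qquad
  t_i = \beta(s_i - s_{i-1}) + (1-\beta)t_{i-1}, \qquad
  \hat x_i = s_i + t_i,$$

is initialised with $s_1 = x_1$, $t_1 = x_2 - x_1$, which makes the
smoother exact (zero one-step error, exact $h$-step continuation
$s + m\,t$) on any affine series for any weights — a property the tests
exercise over a weight grid. When weights are `"optimize"` they are chosen
by a deterministic grid search ($0.05$ to $0.95$ in steps of $0.05$) over
the in-sample one-step SSE, refined by Nelder–Mead.

The nonlinear half is a small fully-connected network (two hidden layers
of 32 ReLU units, full-batch Adam, 500 epochs, inputs and targets
standardised by training statistics, all seeded) mapping a sliding window
(default $w = 3$) of recent one-step smoothing residuals to the next
residual. Ten annual observations per series cannot train a network, so
residual windows are **pooled across all regions** into one training set —
the per-series alternative was rejected for exactly that reason. The
residual record is taken from smoothing the concatenation of the actual
training values with the smoother's own projection (recorded in the result
metadata as the reading of the sample-augmentation step); since the
projection continues the smoother linearly, the manufactured samples agree
with the training-span residuals.

The hybrid forecast at every lead is *exactly* the smoother's forecast
plus the recursively predicted residual (predictions feed back into the
window), and the test suite asserts this decomposition to $10^{-12}$.
Metrics (MSE, MAE, RMSE, MAPE in percent, $R^2$) are computed on the
held-out span, pooled across regions by default (per-region metrics are
attached where the span allows). The evaluation protocol mirrors an
annual-panel study: train on 2011–2018, test on 2019–2020, forecast to
2030.

## The synthetic-data generator

`generate_panel()` simulates the generative counterpart of the analysis
model: resource covariates first (log-normal around realistic national
levels — NHI 0.55, NBHI 5.5, NHTP 7.0 per 1000 population, with mild
Leroux spatial smoothing, annual log-trends of 1–3% and 2% observation
noise), then EPR conditional on them through the log-linear model with a
Leroux spatial field, a drift-plus-random-walk year effect, iid
interaction and observation noise, around a national baseline of 10
percentage points. Scenario defaults (31 regions, 10 years,
$\beta = (0, 0.01, 0.04)$, $\tau_\varphi = 0.15$, $\rho = 0.8$, trend 3%
per year, interaction and noise scales 0.02) keep simulated EPR in the
10–20% range of a realistically ageing country. The true latent effects
are returned with the panel so recovery can be scored.

What the generator does *not* emulate: population weighting (all regions
count equally in the national baseline), reporting artefacts and
administrative revisions, boundary changes, and any calibration to a
specific country's observed values. Passing tests therefore demonstrate
that the machinery recovers known structure of the assumed model class,
not that any particular national dataset satisfies that model.

Adjacency options are a rook-contiguity grid, a chain, and the
relative-neighbourhood graph of seeded uniform points (planar and
connected, since it contains the minimum spanning tree) as a stand-in for
irregular provincial contiguity. One empirical note from validation: on a
36-region lattice the realised spatial autocorrelation of a Leroux field
with $\rho = 0.95$ varies widely between draws, so detection-rate
properties are exercised on an $8\times 8$ lattice where the
permutation test has adequate power.

## Degenerate inputs and numerical conventions

* Zero-variance vectors are rejected by every Moran statistic (the
  denominator vanishes); constant chains return Geweke $z = 0$ with a
  warning flag; MAPE refuses zero true values and $R^2$ refuses constant
  truth, naming the offending index.
* Permutation pseudo p-values add 1 to numerator and denominator, so
  $p \in (0, 1]$ and is never zero.
* All randomness — panel generation, permutations, MCMC, network
  initialisation — flows from explicit integer seeds; every pipeline
  stage is bit-reproducible, and the end-to-end test runs the full
  31-region pipeline twice and requires identical output.
* Island regions are retained everywhere: the CAR prior stays proper
  ($\rho < 1$), their spatial lag is 0, and LISA labels them ISOLATE.

## Limitations

* The spatial relative levels feeding the IAR come from response-only
  fits; measured covariates are deliberately excluded there so that
  $\exp(S_i)$ captures the *total* regional departure, but this means the
  IAR inherits any unmodelled confounding between space and time.
* A single-chain Geweke check is the only convergence diagnostic;
  multi-chain $\widehat R$ is out of scope by design.
* The forecaster assumes each series is trend-plus-stationary-residual;
  series with structural breaks inside the short training span will
  defeat both halves of the hybrid.
* The comparison regressors of a full benchmarking exercise (linear
  regression, tree ensembles, support-vector and k-nearest-neighbour
  regressors, gradient boosting, multilayer perceptrons) are not
  reimplemented; `make_windows()` exposes the supervised dataset so any
  external regressor can be plugged in.

```{r, eval = FALSE}
# a compact end-to-end run
library(agematch)
sc <- synthetic_scenario(seed = 7)
w <- generate_adjacency(31, "random_planar", seed = 7)
panel <- generate_panel(sc, w)
moran_time_series(panel, "epr", w, seed = 7)
iar <- iar_series(panel, w, bst_model_spec("epr", seed = 7))
ets_dnn_forecast(iar$iar_st, panel_years(panel),
                 train_end = 2018, test_end = 2020, horizon = 10, seed = 7)
```
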