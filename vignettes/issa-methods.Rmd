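---
title: "Methods: integrated step-selection analysis with experience and social moderators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated step-selection analysis with experience and social moderators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issa)
```

## The model

The package estimates habitat selection at the step scale for GPS-tracked
animals — the motivating system is scimitar-horned oryx reintroduced into
the Sahelian grasslands of central Chad, tracked at mixed 1/2/4-h schedules
across two release cohorts. A *step* is the straight-line displacement
between consecutive 4-h fixes. For each observed ("used") step we sample
nine "available" steps that share its origin: step lengths come from a
gamma distribution and turning angles from a von Mises distribution, both
fitted to the observed steps of the same period. The used step plus its
nine alternatives form one *stratum*, and selection coefficients
$\beta$ maximize the stratified conditional (partial) log-likelihood

$$\ell(\beta) = \sum_s \left[\beta^\top x_{s,\text{used}} -
\log \sum_{j \in s} \exp(\beta^\top x_{s,j})\right].$$

Step length and its logarithm enter as covariates to correct the
selection-free movement kernel, the iSSA device that makes the gamma
kernel's tentative parameters innocuous: differences between the tentative
and the true gamma density are linear in $(s, \log s)$ and are absorbed
exactly by these two terms. Because one animal contributes many
non-independent strata, the reported standard errors come from a
cluster-robust sandwich $A^{-1} B A^{-1}$, with $A$ the observed
information and $B$ the outer product of per-animal score sums.

Exponentiating a coefficient gives the *relative selection strength*
(RSS): the multiplicative change in the probability of choosing a location
per one (standardized) unit of the covariate, all else equal.

### Covariates

Environmental layers live on a common 500-m grid:

* **aNDVI** — NDVI anomaly: the current 16-day NDVI composite minus a
  multi-year baseline mean. The default baseline is *seasonal*: the mean of
  the same composite slot (position in the annual 23-composite cycle)
  across the baseline years, so that an ordinary year has anomaly near
  zero year-round and the anomaly reads as greenness relative to the
  long-term seasonal cycle. A single grand-mean baseline is available via
  `mode = "grand"`; the choice is configurable because either reading is
  compatible with "mean NDVI over a multi-year period".
* **dNDVI** — 16-day change, `NDVI_t - NDVI_(t-16)`: short-term greening
  (positive) or drying (negative).
* **elevation** and **TRI** — Riley's terrain ruggedness index, the root
  of the summed squared elevation differences to the 8 neighbors; border
  cells use the neighbors that exist.
* **temperature** — a time-indexed composite series like NDVI; its cadence
  is whatever the input files carry.

Step endpoints read each time-indexed layer from the most recent composite
at or before the step's end time (no look-ahead), by nearest cell —
the grids are already at the analysis resolution; bilinear point
extraction is available. Strata in which any row lacks any covariate
(off-map point, no-data cell) are dropped whole, because the conditional
likelihood needs complete matched sets; the count of dropped strata is
reported.

Two *moderators* vary between but not within strata and therefore enter
only through interactions:

* **experience** — fractional days since the animal's release;
* **group size** — the chain-rule social group: animals within 200 m of
  at least one other member belong to the same group (connected components
  of the proximity graph, computed per 4-h bin from each animal's
  resampled fix; an animal alone is a group of 1). Single-linkage
  clustering cut at the threshold distance gives exactly these components.

Both are evaluated at the stratum's start fix — the decision point — and
replicated to all rows.

### Candidate models and selection

Four nested candidates per period (dry = January–June, wet =
July–December, by the month of the step's start): M1 environmental only;
M2 adds experience interactions; M3 adds group-size interactions; M4 adds
both. All tiers carry `sl`, `log_sl`, the five environmental mains and
quadratics for aNDVI, dNDVI and temperature; the temperature quadratic and
temperature interactions are restricted to the dry period by default,
where thermal stress plausibly bends the response (configurable). Base
covariates are centered and scaled by the sample SD over all rows of the
period's strata; quadratics and interactions are products of the
standardized bases and are *not* re-standardized, so a moderator level of
$\pm 1$ keeps its meaning of one SD. Candidates are ranked by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $n$ = the number of
strata — the independent contributions to the likelihood; the literature
does not pin this $n$ down, so the choice is stated rather than inherited.
A VIF screen (threshold 4) flags collinear designs.

Moderator *main effects* are constant within strata: the conditional
likelihood cannot identify them, and the fitter rejects stratum-constant
columns. `build_design()` therefore excludes them (with a warning);
`keep_inestimable = TRUE` puts them back for inspection of exactly why
they fail. Published coefficient tables for this kind of analysis do print
such rows; the package trades table mimicry for identifiability.

### Predictions

`log_rss_curve()` evaluates
$\log\mathrm{RSS}(x; x_{\mathrm{ref}}) = \beta_{\mathrm{lin}}(x-x_{\mathrm{ref}})
+ \beta_{\mathrm{quad}}(x^2-x_{\mathrm{ref}}^2) + m\,\beta_{\mathrm{int}}(x-x_{\mathrm{ref}})$
on a grid, with $m \in \{-1, 0, +1\}$ the moderator level in SD units and
the reference at the period mean (the standardized zero), where the curve
crosses RSS = 1. Pointwise 95% bands use the delta method on the robust
covariance, symmetric on the log scale.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| resampling interval | 4 | h | common denominator of the 1/2/4-h collar schedules |
| resampling tolerance | ±30 | min | 12.5% of the interval; admits jittered schedules without conflating fixes |
| available steps | 9 | per used step | the matched-set size of the analysis |
| chain-rule threshold | 200 | m | the field definition of a social group |
| analysis resolution | 500 | m | balances covariate grain against 4-h movement capacity |
| dry months | 1–6 | calendar months | the precipitation regime split |
| step-length floor | 1 | m | below GPS error; keeps `log(sl)` finite for stationary fixes |
| Newton tolerance | 1e-8 | gradient max-norm | far below any scientific resolution |
| VIF threshold | 4 | – | conventional collinearity screen |

## The synthetic-data generator

Field movement data for this system are not redistributable, so the
package ships a generator with known truth; it is first-class, tested code.

The landscape is a stack of Gaussian random fields (FFT-smoothed white
noise on a torus): a static elevation field (mean 300 m, SD 60 m, long
correlation range), NDVI composites every 16 days built from a spatial
base, a seasonal sine with spatially varying amplitude, smooth
per-composite noise, and a planted anomaly field in the study year (what
aNDVI should recover); temperature adds a seasonal cycle, an elevation
lapse and smooth noise. Defaults are 200 × 200 cells at 500 m (100 km on
a side) over 5 years, so a 4-year anomaly baseline precedes the study
year. The extent matters: on test-sized grids of ~30–50 km, simulated
walks of 300 steps hit the boundary often, and boundary reflection
distorts realized kernels enough to attenuate coefficients on
short-range covariates such as TRI; at 100 km boundary contact is
negligible, which is also the realistic regime for a reserve spanning
hundreds of kilometers.

Tracks follow the fitted model's own logic run forward: each animal draws
50 candidate steps from the true gamma/von Mises kernel and picks one with
probability $\propto \exp(u)$, where $u$ adds the environmental
coefficients and the experience/group-size interaction terms on
standardized covariates at the candidate endpoint. Fifty candidates
(versus 9 available at analysis) keep the discrete-choice approximation of
the continuous SSF density tight. Group cohesion is a quadratic attraction
toward the group's current centroid added to $u$; every member still makes
its own habitat choices, positions update synchronously, and the planted
group sizes are what chain-rule detection recovers as the modal size.
The true coefficients live on the scale of the landscape's marginal
moments over the simulation window (stored in the truth manifest), so
recovery experiments standardize with those constants and compare like
with like.

Profiles: `tiny` (2 animals × 50 steps) exercises the pipeline end to end
in seconds; `recovery` (15 independent animals × 300 steps, two release
cohorts at −400/−30 days, four environmental effects plus two experience
interactions) is the parameter-recovery oracle; `grouped` (12 animals in
cohesive groups of 2/4/6) feeds the chain-rule checks; `moderated`
(32 animals — the study's collar count — in 9 groups of sizes 1–8,
releases scattered over ~1.5 years) feeds the model-selection experiment.
In the selection experiment's no-effect world the interaction
coefficients *and* the group attraction are zero: attraction itself is a
real group-size moderation of movement (cohesive groups take shorter,
centroid-biased steps), so a null world must be asocial, not merely
interaction-free.

What the generator does *not* emulate: GPS error and collar failure,
cloud/QA artifacts in NDVI, true Sahelian phenology, births/deaths and
group fission–fusion dynamics beyond transient proximity, and
behavioral states (resting vs traveling). Passing tests therefore show
that the estimator recovers the generating process of this family — not
that field data meet its assumptions.

## Numerical choices

* Gamma fit: profile MLE (root of the shape score, scale = mean/shape),
  with the log-likelihood checked against the method-of-moments start.
* Von Mises concentration: root of $A_1(\kappa) = \bar R$ using
  exponentially scaled Bessel ratios, stable for large $\kappa$;
  $\bar R \approx 0$ returns $\kappa = 0$ (uniform) rather than an error.
  Sampling uses the Best–Fisher rejection algorithm.
* Newton–Raphson with analytic gradient/Hessian, step-halving on
  likelihood decrease, hard stop at 50 iterations; a step with max-norm
  above 25 on standardized columns is reported as separation. Softmax
  weights are computed with per-stratum max subtraction.
* Angles wrap to $(-\pi, \pi]$; turning angles need a previous step in the
  same burst, so the first step of each burst seeds no stratum.
* The cluster-robust covariance carries the CR1 small-sample multiplier
  $G/(G-1)$ over the $G$ animal clusters, and the recovery experiment's
  confidence intervals use a $t_{G-1}$ reference — the standard pairing
  when clusters number in the tens; the plain sandwich is known to
  undercover there. Reported p-values use the normal reference.
* Ties in AICc break toward the smaller model.
* All randomness descends from one integer seed through named substreams
  (landscape, tracks, strata, …), so stages are reproducible in isolation
  and available-step sampling is bit-reproducible under the same seed.

## Problem sizes used by the shipped experiments

Recovery: 20 replicates of the `recovery` profile (≈ 4,400 strata each);
model selection: 2 × 20 replicates of the `moderated` profile (≈ 9,300
strata, four tiers each). These sizes give per-component CI-coverage
estimates with ±9% binomial noise at 20 replicates, which is why the
coverage acceptance bound (≥ 80% observed for a nominal 95% interval)
carries finite-sample slack.

## Known limitations

* One population-level kernel per period; no per-animal kernels and no
  iterative re-estimation of kernel parameters from the fitted movement
  coefficients (single-pass iSSA).
* No random effects: individual variation is absorbed only by the
  cluster-robust variance, and — as in any likelihood-based comparison on
  clustered data — AICc differences are computed from the raw likelihood,
  so heavy within-animal dependence can overstate the support for richer
  models. The simulation experiments quantify this under the package's
  own generating conditions, not beyond them.
* Chain-rule grouping uses one fix per animal per 4-h bin; whether animals
  stayed within the threshold for the whole bin is not assessed.
* Coordinates must arrive projected in meters; the package does no
  geodesy and rejects longitude/latitude input.
* Rasters are read and written as single-band ESRI ASCII grids with dated
  filenames; reprojection, masking and acquisition live upstream.
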