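---
title: "Hierarchical Bayesian discrete-choice resource selection"
author: "choicesel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian discrete-choice resource selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`choicesel` analyses *used-versus-available* habitat data collected as
**choice sets**: one location a bird actually used, paired with two
available locations sampled at the same time about 50 m away.  Within a
set, the utility of location $j$ is a linear score

$$V_j = \mathbf{x}_j'\boldsymbol\beta,$$

where $\mathbf{x}_j$ stacks six vegetation covariates (litter depth,
understory foliage density, sapling/pole/saw timber stem densities,
canopy cover), distance to nonforest edge, and the six
vegetation-by-edge interactions — 13 coefficients.  The probability the
used location is the one chosen is the conditional (multinomial) logit

$$\Pr(\text{choose } j) = \frac{e^{V_j}}{\sum_{k=1}^{3} e^{V_k}}.$$

Only within-set covariate *differences* are identified, so there is no
intercept and no alternative-specific constants: alternatives are
unlabelled and exchangeable, and anything constant across the three
locations of a set cancels.  This is also why the design is robust to
between-set variation in availability, season or individual age — each
set is its own comparison.

Two models share this likelihood:

* **Nest model** (`dcfit(model = "nest")`): one coefficient vector
  $\boldsymbol\beta$ shared by all nest choice sets, with vague normal
  priors $\beta_k \sim N(0, \text{precision } 0.01)$ (variance 100).
* **Postfledging model** (`dcfit(model = "postfledging")`): juveniles
  are radio-tracked repeatedly, so sets from one bird are not
  independent.  Each individual-stage unit $i$ in developmental stage
  $s$ gets its own vector
  $\beta_{isk} \sim N(\mu_{sk}, \sigma_{sk})$, with
  $\mu_{sk} \sim N(0, \text{precision } 0.01)$ and diffuse
  $\Gamma(1, 10^{-4})$ priors on each precision
  $\tau_{sk} = \sigma_{sk}^{-2}$.  Birds observed in several stages
  contribute one vector per stage; birds with few sets shrink toward
  the stage's population distribution.

Stages follow developmental milestones: *early dependent* (first week
out of the nest, day $\le 7$), *late dependent* (day $\ge 8$, still fed
by parents) and *independent* (no parental care, a behavioural flag).
Day 8 is assigned to the late-dependent stage so that the partition is
contiguous and no data are dropped.  When one stage's sets are too
homogeneous to support separate population-level coefficients, the
late-dependent and independent stages can be pooled
(`stage_grouping(pool_late_independent = TRUE)`); the pipeline does this
automatically on non-convergence when configured.

### On the priors

"$N(0, 0.01)$" is read in the mean/precision parameterization (variance
100), the convention of BUGS-family samplers; an SD-of-0.1 prior would
be anything but vague.  The $\Gamma(1, 10^{-4})$ prior sits on the
precision (equivalently an inverse-gamma on the variance).  Note a
consequence worth knowing: a nearly flat prior on the precision places
most of its mass at very small $\sigma$ (under the prior,
$\Pr(\sigma < 0.1) \approx 0.99$), so unless the data clearly demand
between-individual heterogeneity the posterior for $\sigma$ concentrates
near zero and the hierarchical model behaves like a pooled one.  This is
a property of the specified model, not of the sampler; the recovery
study below quantifies its effect on interval calibration.

## Sampling

No sampler is prescribed by the model, only the posterior.  The default
is adaptive random-walk Metropolis within Gibbs, written in C++:

* each unit-level coefficient $\beta_{isk}$ is updated by a
  per-coordinate random walk against its own sets' likelihood plus the
  $N(\mu_{sk}, \sigma_{sk})$ prior;
* $\mu_{sk}$ and $\tau_{sk}$ have conjugate Gibbs updates;
* two **interweaved non-centered moves** follow: holding the unit
  deviations fixed, a translation move on $\mu_{sk}$ (shifting every
  unit of the stage together) and a Metropolis move on $\log\tau_{sk}$
  (rescaling every deviation together).  Without these the centered
  Gibbs scheme moves $\mu$ in steps of order $\sigma/\sqrt{n}$ and can
  take effectively forever to traverse the $\sigma \approx 0$ funnel
  that this prior favours.  Chains must also *start* with dispersed
  unit coefficients: if all $\beta_{is}$ initialise exactly at $\mu_s$,
  the first precision draw sees zero spread and the chain is born in
  the degenerate corner.

Proposal scales adapt only during burn-in (windowed, targeting a
0.23–0.44 acceptance rate), so retained draws come from a fixed kernel.
Defaults: 3 chains, burn-in half of `n_iter`, overdispersed starting
values (`init_sd = 0.5`), thinning sized to retain at most ~2000 draws
per chain.  Convergence is judged by the split-chain Gelman–Rubin
diagnostic with the conventional inclusive threshold
$\hat R \le 1.1$ on *all* monitored parameters ($\mu$, $\sigma$, and
every $\beta_{is}$).  Non-convergence is a reported state with a
warning, never a silent failure and never an exception — the remedy
(more iterations, or stage pooling) is the caller's decision.

All likelihood evaluations use the max-shifted log-sum-exp; raw
utilities are never exponentiated.

## Covariate scales

The published analysis does not say whether covariates entered raw or
standardized, and "one unit" selection-ratio language cannot resolve it.
Both schemes are supported; the default is the pooled z-score over all
locations of the dataset passed to `dcfit()` (used and available
alike), so coefficients are per-SD effects and the seven covariates —
whose raw scales span four orders of magnitude — are comparable.  The
scaling record is kept with the fit, and probability-of-use curves are
reported back on original field scales.  Interactions are formed from
the covariates on the same scale as the mains, never re-centered
separately.  Edge distance enters untransformed (meters before
standardization); a log transform was considered and rejected as an
undocumented extra assumption.

## Posterior summaries

For each coefficient: posterior mean, central 95% credible interval,
and $f$ — the proportion of the posterior sharing the sign of the mean
(draws exactly at zero count as agreeing; an exactly-zero mean has no
direction and yields $f = 0.5$).  The **selection ratio** $e^\beta$ is
the multiplicative change in relative selection probability per
one-unit covariate change; it is computed from the population-level
$\mu$ for juvenile stages and from the shared $\beta$ for nests, and it
is flagged *ineligible* when the covariate's edge interaction is
strongly supported ($f \ge 0.90$), because selection then depends on
more than one coefficient.  The ratio's interval is the exponentiated
coefficient interval (identical to percentiles of exponentiated draws,
by monotonicity); the ratio's point estimate is $e^{\bar\beta}$, not
the mean of $e^\beta$ draws.

**Estrella's $R^2$** summarises fit against the equal-probability null
$L_0 = n\log(1/3)$:

$$R^2 = 1 - \left(\frac{\log L}{L_0}\right)^{-(2/n)L_0},$$

0 at random prediction and 1 at perfect prediction.  $\log L$ is
evaluated at posterior means — individual-level means for the
hierarchical model, since those are the coefficients that generated the
choices.  A posterior-mean-deviance variant would be slightly more
conservative; the point-estimate convention is used because it is the
one a refit can compare against.

**Relative probability-of-use curves** sweep one covariate over its
observed range with all others held at their dataset means, per
posterior draw, and are anchored so the curve equals 1 at the
dataset-mean focal value (anchoring changes the y-scale only, never the
shape — unanchored curves differ by a constant factor).  When the
focal-by-edge interaction is supported ($f \ge 0.90$) a near-edge (10th
percentile of observed edge distances) or far-from-edge (90th
percentile) scenario must be chosen; both utilities in the anchor ratio
share the scenario's edge distance.

## The synthetic generator

`generate_dataset()` emulates the *statistical* structure the analysis
assumes — nothing more: covariate triples drawn from configurable
marginals with within-set correlation $\rho$ (a Gaussian copula shares
a set-level latent normal; default $\rho = 0.3$ for vegetation, 0.9 for
edge distance, since the three locations of a set sit within ~50 m of
one another), individual coefficients from stage-specific normals, and
choices drawn through the *same* design-matrix and softmax code used in
inference.  Utilities are computed on the pooled z-score scale of the
emitted dataset, so the generator's likelihood is exactly the fitted
one and ground-truth coefficients are per-SD effects.

Default marginals span the field protocol's natural ranges (canopy
0–100%, understory 0–1, stem densities 0–2000/ha, litter 0–10 cm, edge
10–400 m); they are presets, not estimates of any real landscape.
Simulated independence begins at a configurable day (default 20).  The
`"fieldlike"` preset reproduces the shape of a telemetry season
(39/30/24 juveniles across the three stages, 2–8 sets each — 100–250
sets per stage — plus 170 nest sets); the `"recovery"` preset (2 stages
× 40 individuals × 12 sets) is the workhorse for calibration studies;
`"null"` zeroes the population means.

What the generator does **not** emulate: spatial structure and
autocorrelation beyond the within-set copula, observation error in the
vegetation measurements, transmitter loss or mortality, and any
covariate distribution fitted to real data.  Passing recovery tests
therefore demonstrates that the inference machinery targets the model
it claims to — not that the model is adequate for any particular field
system.

## Calibration evidence and problem sizes

The test suite and `scripts/acceptance.R` compute, among others:

* exact agreement (to $10^{-9}$) of the dataset likelihood with an
  independently coded naive implementation on 10-set instances;
* posterior means within 0.05 (standardized scale) of a directly
  optimized ML fit on 300 sets under vague priors;
* posterior mean and SD within 2% of a dense-grid numerical posterior
  for a one-covariate model on 20 sets;
* over 20 replicates of the recovery preset: 95% CRI coverage of the
  population means, and near-zero bias under the null preset.  Because
  the precision prior shrinks $\sigma$ toward zero when heterogeneity
  is weakly identified (see above), $\mu$ intervals run slightly
  narrow, and coverage sits a little below nominal rather than at 95%.

Replicate fits in these studies use 3 chains of 2,500–3,000 iterations
(half burn-in); single illustrative fits use 5,000–20,000.  These sizes
were chosen as the smallest at which the split-$\hat R$ diagnostics and
grid/MLE agreement stabilise on the presets shipped with the package.

## Known limitations

* Choice sets are fixed at 3 alternatives (1 used + 2 available), the
  design of the field protocol; other set sizes are rejected at
  validation.
* Random coefficients are component-wise independent — no covariance
  across the 13 dimensions is estimated.
* All 13 coefficients are hierarchical in the postfledging model; a
  mains-only hierarchy would be a smaller model, but nothing in the
  model description licenses treating interactions differently.
* No GIS: edge distance is consumed as a column.  No model selection
  across covariate subsets, and no multiplicity adjustment of the
  summaries.
* The XLSX-deposited style of field table must be exported to CSV
  before `read_choice_table()` can ingest it; the reader's contract is
  deliberately limited to delimited text.
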