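# choicesel

Hierarchical Bayesian discrete-choice (conditional logit) resource
selection for nest sites and postfledging songbirds.

## The problem

Radio-tracking studies of forest songbirds ask whether the vegetation a
bird selects changes over the breeding season — between nest-site
selection and the successive developmental stages of its fledglings
(early dependent, late dependent, independent).  The data arrive as
**choice sets**: each time a bird is located, the used location plus two
available locations ~50 m away are sampled for litter depth, understory
foliage density, sapling/pole/saw timber densities, canopy cover and
distance to nonforest edge.  Because each set is its own within-moment
comparison, the analysis is immune to drift in availability, season or
age that plagues pooled used-versus-available regressions.

`choicesel` is for analysts of such data: it models the utility of
location *j* in a set as

    V_j = x_j' beta        (13 coefficients: 6 vegetation mains,
                            edge distance, 6 vegetation x edge terms)

with choice probability `exp(V_j) / sum_k exp(V_k)` over the 3
alternatives.  Nest sets share one coefficient vector (vague
`N(0, precision 0.01)` priors).  Postfledging birds are observed
repeatedly, so each individual-stage combination gets its own vector
drawn from stage-level normal population distributions,
`beta_is ~ N(mu_s, sigma_s)`, with `Gamma(1, 1e-4)` priors on the
precisions `1/sigma_s^2`.  Fitting is by an adaptive
Metropolis-within-Gibbs sampler (C++) with interweaved non-centered
moves, split-chain Gelman–Rubin diagnostics (`Rhat <= 1.1`, inclusive),
and posterior summaries in the field's house style: mean, 95% CRI, the
directional confidence *f*, selection ratios `exp(beta)`, Estrella's
pseudo-R², and relative probability-of-use curves at near-edge/far-edge
scenarios.  A synthetic choice-set generator with known ground truth
makes every stage of the pipeline testable without field data.

## Worked example

Simulate a field-shaped season (170 nest sets; 39/30/24 juveniles over
three stages), fit both models, and summarise:

```r
library(choicesel)

d <- generate_dataset(sim_config(preset = "fieldlike", seed = 1))$data
d
#> Choice-set data: 579 sets, 209 individuals, species = flycatcher
#>   sets per stage: early_dependent=117, independent=117, late_dependent=175, nest=170

nest <- dcfit(d, model = "nest",
              control = mcmc_control(n_iter = 10000), seed = 1)
nest
#> Bayesian discrete-choice resource-selection fit (nest model)
#>   choice sets: 170
#>   chains: 3 x 10000 iterations (burn-in 5000 , thin 2 )
#>   max Rhat: 1.002 (converged)
#>   Estrella's R2: 0.233

tab <- coefficient_table(nest)
tab[tab$covariate == "canopy_cover",
    c("covariate", "mean", "cri_lo", "cri_hi", "f", "selection_ratio")]
#>      covariate  mean cri_lo cri_hi f selection_ratio
#> 6 canopy_cover 0.601   0.34  0.874 1            1.82
```

Reading: a 1-SD increase in canopy cover multiplies the relative
probability a nest site is selected by ~1.8 (95% CRI from
`exp(cri_lo)` to `exp(cri_hi)`), with `f = 1` — essentially all
posterior mass agrees the effect is positive.  Estrella's R² of 0.23
says the model predicts choices modestly better than the
equal-probability null (`n log(1/3)`).  Ratios are suppressed
(`eligible = FALSE`) wherever the covariate's edge interaction has
`f >= 0.90`, since selection then depends on two coefficients; in that
case plot the relative probability-of-use curve instead:

```r
pf <- dcfit(d, model = "postfledging",
            control = mcmc_control(n_iter = 15000), seed = 2)
uc <- use_curve(pf, "understory_density", scenario = "far",
                stage = "late_dependent")
plot(uc)   # posterior mean curve with 95% CRI band, anchored at 1
```

The hierarchical fit reports population means per stage (`coef(pf)` is
a stages × coefficients matrix), and `summary(pf)` prints the full
stage-by-covariate table with convergence state.

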