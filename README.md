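# canopymr

Bayesian mark-recapture and abundance analysis for canopy treefrogs
under prescribed fire.

## The problem

In fire-maintained pine flatwoods, a treefrog confronted by a
prescribed burn can flee, climb, shelter in place, or die — and
ground-level surveys cannot tell these apart.  `canopymr` implements
the analysis of a before-after-control-impact (BACI) pipe-refugium
experiment built to separate those mechanisms: PVC refugia at four
heights (3 m, 6 m, 9 m, 9+ m) in 12 mature pines split between units
burned during the study and reference units burned the year before,
checked biweekly over 14 occasions with individually marked frogs.

It is aimed at quantitative ecologists who want the full pipeline —
data model, likelihoods, samplers, model comparison, reporting — as
tested, reusable functions rather than a one-off analysis script.

## The models

**Multi-state mark-recapture.**  Latent states are the height strata
h = 1..H plus an absorbing, unobservable dead state.  Between
occasions, an individual at height h survives with apparent survival
φ_h and, given survival, moves to height h′ with probability α_hh′
(rows of α are simplices), so the transition matrix has entries
ψ_hh′ = φ_h α_hh′ and ψ_h,dead = 1 − φ_h.  A live frog at height h is
detected at h with probability p_h and nowhere else.  The capture-
history likelihood conditions on first capture and marginalizes latent
paths with the hidden-Markov forward algorithm (C++).  Burned and
reference groups are fitted separately; fire effects are read off the
posterior of the transition probabilities, especially the retention
diagonal ψ_hh.

**Abundance.**  Counts per tree j and occasion i follow
Counts_ij ~ Poisson(λ_ij), log λ_ij = β_p(i,j) + γ_i + δ_j, with
occasion and tree random effects γ_i ~ N(0, σ_γ²), δ_j ~ N(0, σ_δ²)
and a three-level fire condition (baseline / 0–6 weeks post-fire /
6+ weeks post-fire, 42-day window).  Candidate models (full,
random-effects-only, single mean) are compared by WAIC with
Akaike-style weights, and treatment questions are answered with
posterior contrasts P(A > B).

A synthetic-data generator reproduces the whole field design with known
truth (Poisson entry with fire effects, latent Markov movement and
death, imperfect height-specific detection), so every estimator is
validated by parameter recovery without any external data.

## Worked example

```r
library(canopymr)

## simulate the canonical BACI scenario and summarize it
sc <- fireStudyScenario(seed = 1)
ch <- buildCaptureHistories(sc$detections, sc$design)
summarizeDataset(ch, sc$detections)

## fit the multistate model to the reference trees
ref <- studyTrees(sc$design)$tree_id[
  studyTrees(sc$design)$treatment == "reference"]
chRef <- buildCaptureHistories(
  sc$detections[sc$detections$tree_id %in% ref, ], sc$design)
fit <- fitMultistate(chRef, control = mcmcControl(
  seed = 1, iter = 2000, warmup = 2000, thin = 10))
fit
#> PosteriorDraws [multistate]: 8000 draws x 24 parameters, 4 chains
#>   max split R-hat = 1.014, min ESS = 416.6
round(transitionPosteriors(fit)$summary["psi_3_3", ], 3)
#>         from to  mean  q2.5   q25   q50   q75 q97.5
#> psi_3_3    3  3 0.352 0.178 0.282 0.346 0.417  0.55
```

The summary prints:

```
Mark-recapture dataset summary
  individuals:         96
  recaptures:          229
  unidentified:        0
  excluded records:    0
  per-height totals:   3m=60  6m=86  9m=98  9plus=81
  mean captures (all): 3.39
  mean captures (recaptured): 4.01
  recaptured at least once: 76 (79%)
```

i.e. this realization of the generator produced 96 marked individuals
with 229 recaptures spread over the four heights, 3.4 captures per
individual on average — the same bookkeeping shape and scale as the
field study.  The fitted object reports its convergence diagnostics (split
R-hat, effective sample size per parameter), and the
`transitionPosteriors` row gives the posterior mean and quantiles of
the probability of remaining at 9 m between consecutive occasions.

A command-line wrapper over the same functions ships in
`inst/scripts/canopymr` (subcommands `simulate`, `summarize`,
`fit-multistate`, `fit-abundance`, `waic`, `contrast`, `report`).

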