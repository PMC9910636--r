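# marblechain

Bayesian analysis of copying fidelity and feature survival in child
transmission chains.

## The problem

In a transmission-chain experiment, groups of five to six children each
build a marble run after seeing a model: the first child sees an
experimenter's eight-block run, every later child sees their predecessor's
build. Each block carries a **functional** feature (its shape class — ramps,
cubes, and larger blocks that two cubes could replace) and a
**non-functional** one (its colour). Two questions follow:

1. **Dyadic copying fidelity** — with what probability does a child
   reproduce a unit of the model run in front of them, and how does that
   probability depend on feature type, being observed by a peer, age, sex,
   community and chain position?
2. **Feature survival** — how far along the chain do the original run's
   features travel before they are lost for good?

`marblechain` is for researchers running or re-analysing such experiments:
it provides the coding scheme that turns built runs into analysable records,
a fully parameterised synthetic-study generator for method validation, and
the two Bayesian models, fitted by MCMC through JAGS.

## The models

**Individual copying fidelity.** For one feature, the number of matching
units is `y ~ Binomial(n, p)` with `logit(p)` a function of condition
(observed/unobserved), chain position, community, age, sex and their
interactions, plus varying intercepts for child, group and community.
Priors are weakly informative (Normal(0, 1.5) intercepts, Normal(0, 1)
slopes, Exponential(1) SDs). Shape and colour are separate models; results
are reported on the outcome scale as posterior means with 89% percentile
intervals, and differences between settings as contrasts with 89% HPDIs.

**Chain transmission.** Whether an original block's feature is reproduced
at transition stage *t* (given it survived to stage *t*) is Bernoulli with

    logit(p) = alpha[k] + bmono[k] * sum(delta[k, 1:(t-1)]) + varying effects

per stratum *k* = community × condition × feature, where `delta[k, ]` is a
5-simplex with a Dirichlet(2) prior — the monotonic (ordered-categorical)
construction: all six transition probabilities change in one direction with
free step sizes. Survival curves multiply the conditional transition
probabilities within each posterior draw: `S(1) = 1`,
`S(t+1) = S(t) * p_t`.

## Worked example

```r
library(marblechain)

# A synthetic study: 5 communities x 8 groups, known generative parameters
study <- simulate_study(study_config(groups_per_community = 8),
                        true_params(), seed = 1)

# Code the symbolic runs, apply the exclusion cascade
coded <- run_code(study$runs$archive, study$runs$initial, study$roster)
keep  <- apply_exclusions(study$ledger, "individual")$retained
dyads <- study$dyads[study$dyads$child_id %in% keep, ]

# Fit the copying-fidelity model for each feature
fit_shape <- fit_full_model(build_design(dyads, "shape"), sampler_settings(seed = 2))
fit_color <- fit_full_model(build_design(dyads, "color"), sampler_settings(seed = 3))
mean(predict_probability(fit_shape, condition = 0.5))
#> [1] 0.8600482
mean(predict_probability(fit_color, condition = 0.5))
#> [1] 0.5733875
contrast(fit_shape, list(condition = 0.5), list(condition = 0.5), fit_b = fit_color)
#> contrast: mean 0.287, 89% HPDI [0.245, 0.328]
```

The two predicted probabilities are each feature's population-level copying
fidelity on the outcome scale (generative truth 0.85 and 0.55 here), and
the contrast is the shape-minus-colour gap with its 89% highest-density
interval — close to the generative gap of 0.30 at this study size.

Chain-level survival works the same way:

```r
keep_ch <- apply_exclusions(study$ledger, "chain")$retained
chains  <- coded$chains[coded$chains$child_id %in% keep_ch, ]
fit_ch  <- fit_chain_model(chains, chain_settings(seed = 4))
surv    <- survival_table(fit_ch)          # strata x 7 stages
subset(surv, stage == 7 & community == "A")
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/marblechain.R` (subcommands `simulate`, `code`, `fit`, `report`,
`all`).

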