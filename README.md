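# perceptlearn

Trial-by-trial hierarchical Bayesian modelling of perceptual learning in
texture oddball detection tasks.

## The problem

In the visual texture paradigm, an observer views a briefly presented grid
of oriented lines — on half of the trials one element is tilted — followed
by a pattern mask after a stimulus onset asynchrony (SOA) of 15–500 ms, and
reports whether an oddball was present. Performance improves within a
session: the SOA needed for criterion accuracy (the *threshold*) drops with
practice. Researchers studying what modulates this learning (age,
mood-induction condition, arousal) need to separate three components of
change — where performance **starts**, how **fast** it changes, and where
it **asymptotes** — while respecting that accuracy is a noisy Bernoulli
outcome observed one trial at a time, at a different SOA on every trial.

`perceptlearn` is for computational psychophysicists who want that analysis
as a tested, reusable pipeline: a synthetic-data generator shaped like the
2 (age group) × 3 (condition) design, exact-binomial screening of at-chance
participants, hierarchical Bayesian estimation of the learning model, and
effect-versus-null model comparison by bridge-sampling Bayes factors.

## The model

Accuracy on trial *t* at SOA *x* (seconds) follows a chance-floored Quick
(Weibull) psychometric function with lapse rate ε:

```
P(correct) = γ + (1 − γ − ε) · (1 − 2^(−(x/θ(t))^β)),   γ = 0.5
```

so that with ε = 0 the threshold parameter θ is exactly the SOA giving 75%
accuracy. The threshold evolves as an exponentially saturating function of
trial number,

```
θ(t) = exp( A + (S − A) · 2^(−(t−1) / 10^R) )
```

with components of change on link scales: `S` the log starting threshold,
`A` the log asymptotic threshold, and `R` the base-10 log of the
half-change time constant in trials. Each component carries group fixed
effects — age (±0.5), arousal (−0.5 control / +0.5 manipulated), and a
*monotonic* three-level valence effect (stress < control < positive,
parameterized as a total coefficient times cumulative Dirichlet simplex
weights) — plus by-participant Gaussian random effects; the Weibull shape
β is constant over time per participant. Estimation is Hamiltonian Monte
Carlo over an analytically differentiated log posterior (non-centered
random effects, dual-averaging step size, diagonal mass adaptation).
Effect and null models are compared through marginal likelihoods estimated
by the iterative Meng–Wong bridge identity and reported as base-3 log
Bayes factors, where values below −1 (above +1) indicate at least moderate
evidence for the simpler (more complex) model.

## Worked example

```r
library(perceptlearn)

# simulate a study-shaped data set with known ground truth
sim <- simulate_experiment(
  design_spec(n_per_cell = 8, trials_per_block = 100, seed = 11),
  ground_truth(fraction_at_chance = 0)
)

# screen at-chance participants on all trials, then model the first 200
screen  <- exclude_at_chance(sim$trials)
keep    <- screen$participant_id[screen$included]
modelled <- truncate_trials(subset(sim$trials, participant_id %in% keep), 200)

fit <- fit_learning_model(
  modelled, model_spec("full", include_interactions = FALSE),
  mcmc_control(chains = 2, warmup = 500, iter = 400), seed = 7
)
tidy(fit)
```

```
# A tibble: 13 × 5
   term                estimate conf.low conf.high reliable
   <chr>                  <dbl>    <dbl>     <dbl> <lgl>
 1 Asym: Intercept      -2.34     -2.63     -2.05  TRUE
 2 Asym: age            -0.817    -1.12     -0.446 TRUE
 3 Asym: arousal        -0.247    -0.841     0.302 FALSE
 4 Asym: valence         0.0133   -0.399     0.449 FALSE
 5 Start: Intercept      0.858     0.148     1.75  TRUE
 6 Start: age            0.197    -0.719     0.892 FALSE
 7 Start: arousal       -0.630    -2.00      0.601 FALSE
 8 Start: valence        0.388    -0.658     1.45  FALSE
 9 Rate: Intercept       1.53      1.27      1.82  TRUE
10 Rate: age             0.242    -0.180     0.610 FALSE
11 Rate: arousal        -0.260    -0.633     0.159 FALSE
12 Rate: valence         0.180    -0.125     0.503 FALSE
13 PF shape: Intercept   1.24      0.997     1.50  TRUE
```

The data were generated with a true cross-group mean asymptote of −2.4
log-seconds, an age effect of −0.6 (adults reach lower thresholds), and
*no* condition effects; the table recovers exactly that pattern — the age
and intercept rows are reliable (95% credible interval excluding zero),
every arousal/valence row is not. `Asym: Intercept` of −2.34 corresponds
to a threshold of `exp(−2.34) ≈ 96 ms`; `Rate: Intercept` of 1.53 means
half of the log-threshold change is complete after `10^1.53 ≈ 34` trials.

Effect-versus-null comparisons for each age × dimension:

```r
cmp <- run_comparison_suite(modelled, mcmc_control(chains = 2,
                            warmup = 300, iter = 750), seed = 5)
cmp[, c("label", "log3_bf", "verdict")]
#  child x arousal   -4.22  supports-simpler
#  child x valence   -0.24  equivocal
#  adult x arousal    ...
```

`run_pipeline(pl_config(...), out_dir)` chains all stages (simulate/load →
screen → truncate → full model → four comparison pairs → tables) and
writes a manifest with derived stage seeds and file hashes so a rerun
reproduces every artefact.

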