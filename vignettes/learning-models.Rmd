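---
title: "Modelling trial-by-trial perceptual learning with perceptlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trial-by-trial perceptual learning with perceptlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perceptlearn)
```

## The observation model

Every analysis in this package starts from the single-trial level: a
participant sees a texture display at stimulus onset asynchrony (SOA) $x$
seconds before a mask and answers a two-alternative same/different
question. Correctness is Bernoulli with probability given by a Quick
(base-2 Weibull) psychometric function interpolating between a guessing
floor $\gamma = 0.5$ and a lapse-limited ceiling $1 - \varepsilon$:

$$
p(x) \;=\; \gamma + (1 - \gamma - \varepsilon)\,
\bigl(1 - 2^{-(x/\theta)^{\beta}}\bigr).
$$

The base-2 form is chosen so that at $x = \theta$ with $\varepsilon = 0$
the function passes through $0.75$ exactly: the threshold parameter *is*
the 75%-accuracy SOA. With a nonzero lapse the exact 75% point lies
slightly above $\theta$; `solve_threshold75()` returns it in closed form.
Both conventions are exposed, and the midpoint parameter $\theta$ is the
default reported threshold.

Learning enters by letting the threshold decay with trial number $t$
(1-based, continuous across blocks) as an exponentially saturating
function on the log scale:

$$
\theta(t) \;=\; \exp\!\Bigl(A + (S - A)\, 2^{-(t-1)/10^{R}}\Bigr),
$$

with three *components of change*:

| parameter | meaning | units / scale |
|---|---|---|
| $S$ | log starting threshold (value at trial 1, exactly) | log-seconds |
| $A$ | log asymptotic threshold | log-seconds |
| $R$ | log10 of the half-change time constant | log10 trials |

The base-2 kernel makes $10^R$ the number of trials after which half of
the log-threshold change is complete — a more interpretable quantity than
an e-folding constant, though any fixed base is an equivalent
reparameterization. Working on log scales guarantees positivity and puts
plausible effects on a roughly unit scale. The Weibull shape $\beta$ is
modelled as constant over time within a participant (log-normal across
participants); the lapse is fixed at $\varepsilon = 0.01$ by default, with
an optional estimated-lapse mode (a common lapse on a logit scale with a
Beta prior on $2\varepsilon$), since trial counts per participant rarely
identify individual lapse rates.

## Group structure

Each component $c \in \{A, S, R\}$ has participant-level value

$$
c_p \;=\; \mathbf{x}_p^\top \mathbf{b}_c \;+\; m_c(v_p) \;+\;
\sigma_c z_{c,p}, \qquad z_{c,p} \sim \mathcal{N}(0, 1),
$$

with design coding chosen so intercepts are cross-group means: age is
$-0.5$ (child) / $+0.5$ (adult) and arousal $-0.5$ (control) / $+0.5$
(stress or positive — both manipulations raise arousal). Valence is
ordinal with three levels ordered stress $<$ control $<$ positive and is
modelled *monotonically*: the contribution at level $x$ is
$b_v \sum_{i \le x} \zeta_i$ with $\boldsymbol\zeta$ a 2-simplex under a
flat Dirichlet prior. This constrains the control condition to lie between
the two manipulated conditions without forcing equal spacing; within every
posterior draw the three contributions are ordered (in one direction or
the other), never non-monotone.

Four model structures are provided:

* **full** — both ages, all conditions; age, arousal and monotonic valence
  effects on each component, optionally with age interactions (the
  19-coefficient layout). The age × valence interaction shares the
  per-component simplex with the valence main effect; giving each
  monotonic term its own simplex is the other defensible choice, but at
  these sample sizes two simplexes per component are poorly identified
  and the shared-simplex model keeps one interpretable ordering per
  component.
* **arousal** — one age group, all conditions, a binary arousal contrast.
* **valence** — one age group, stress and positive conditions only, a
  binary contrast ($-0.5$ stress / $+0.5$ positive); with the control
  condition excluded a monotonic term would be meaningless.
* **null** — no condition effects, random effects retained. The
  comparison partner for the per-age models, always fit to the identical
  data subset as its effect partner.

## Priors

The defaults are weakly informative and scaled to the task (SOAs of
15–500 ms, a few hundred trials):

| parameter | prior | rationale |
|---|---|---|
| $A$ intercept | $\mathcal N(-2.5, 1)$ | $e^{-2.5} \approx 82$ ms, mid-range SOA |
| $S$ intercept | $\mathcal N(0, 1.5)$ | starting thresholds up to seconds |
| $R$ intercept | $\mathcal N(\log_{10} 50, 0.7)$ | half-change within 1–1000 trials |
| condition / age coefficients | $\mathcal N(0, 1)$ | unit log-scale effects |
| random-effect SDs | half-$\mathcal N(0, 1)$ | |
| log shape | $\mathcal N(\log 3, 0.5)$ | typical psychometric slopes |
| simplex $\boldsymbol\zeta$ | Dirichlet(1, 1) | flat over orderings |

The $R$ prior doubles as a soft bound: when a participant shows no
learning, $S$ and $A$ alias, and prior mass keeping $10^R$ within a few
multiples of the session length prevents the rate from wandering off.
All priors are proper — a requirement for marginal likelihoods to exist —
and `pl_priors()` makes every location and scale configurable.

## Computation

The joint log posterior (Bernoulli likelihood through the PF, priors, and
the Jacobians of the log, logit and simplex transforms) is evaluated with
its analytic gradient in compiled code; random effects are non-centered
throughout. Sampling is plain Hamiltonian Monte Carlo with leapfrog count
jittered uniformly up to `max_leapfrog` (default 64), dual-averaging step
size targeting 0.8 acceptance, and a diagonal mass matrix estimated from
the 30–70% warmup window, after which step-size adaptation restarts under
the new metric. Transitions with non-finite energy or an energy error
above 1000 count as divergences. Per-parameter split-$\hat R$ and bulk
effective sample size are computed on every fit; thresholds
($\hat R > 1.01$, divergences $> 0$) raise warnings rather than errors.
Chains run serially with seeds derived from a single fit seed, so a fit is
bit-reproducible.

Marginal likelihoods use the iterative Meng–Wong bridge identity: the
posterior draws are split randomly in half, a multivariate normal proposal
is moment-matched to one half (with light diagonal shrinkage,
$\lambda = \min(0.5,\, d / (4 n_{\text{half}}))$ — heavy shrinkage erases
posterior correlations and destroys proposal overlap), and the estimator
iterates on the other half to relative change $10^{-8}$ (at most 1000
iterations). The Monte Carlo error is estimated by recomputing the
estimator on five paired blocks of the evaluation draws. Bridge estimates
in a few hundred dimensions want draws: budgets of 1500+ total draws per
model are used in the calibration tests and $\ge 4000$ is a sensible
default for final analyses. Bayes factors are reported as
$\log_3 \mathrm{BF}$ with $\pm 1$ as the moderate-evidence bounds; the
boundary value itself is classified as equivocal (strict inequalities).

## The synthetic-data generator

`simulate_experiment()` emulates the design the models are meant for: 2
age groups × 3 mood conditions, `n_per_cell` participants per cell
(default 24), two blocks of 210 trials, SOAs drawn uniformly from {15, 30,
60, 90, 120, 300, 500} ms (a balanced-within-block option exists; the
design leaves the assignment scheme open and uniform is the default), an
oddball on half the trials, and Bernoulli correctness from the exact model
above. Default ground truth uses round values on the scales such tasks
produce: cross-group mean asymptote $-2.4$ (children $-2.1$, adults
$-2.7$ — about 122 vs 67 ms), start intercept $0.6$ with a $+1.0$ age
effect, rate intercept $1.7$ ($\approx 50$ trials to half-change, so most
learning is complete within the 200-trial analysis window), log shape
$1.2$, random-effect SDs $(0.5, 0.8, 0.5, 0.2)$, lapse $0.01$, and **zero
condition effects** — the no-effect configuration is the reference
condition the comparison machinery is calibrated against. A 10% fraction
of participants responds at chance on every trial to exercise the
exclusion filter. A between-block "mood-booster" effect is *not*
simulated by default; an optional additive block-2 offset on $A$ exists
for sensitivity studies.

What the generator does **not** emulate: late-session fatigue or vigilance
decrements (the reason real analyses truncate to the first 200 trials —
simulated data are stationary, so truncation is exercised mechanically,
not scientifically), sequential dependencies, oddball-present/absent
asymmetries, response bias, or reaction times. Passing tests therefore
show that the pipeline recovers the model's own structure at realistic
sizes and noise levels, not that the model is adequate for any particular
real data set.

## Screening and truncation

Participants whose overall accuracy is not significantly above 50% by a
one-tailed *exact* binomial test ($p < .05$, strict) are excluded;
`binomial_screen_p()` computes the exact tail (at $n = 420$ a normal
approximation would differ only in the fourth decimal, but exactness is
free). Screening uses **all** trials and precedes truncation to the
modelling window (default: first 200 trials), matching the logic of
screening on everything you observed while modelling the window you
trust. For pure-chance responders, the discrete test includes at slightly
under the nominal 5% rate.

## Problem sizes in the test suite

The shipped tests run the full machinery at deliberately chosen scales:
parameter recovery uses 24 participants × 200 trials per age (the
design's cell sizes scaled to desk time) over 20 seeded replicates with
reduced draw budgets (2 × 300 draws); Bayes-factor direction calibration
uses 10 zero-effect replicates at 4 participants per cell × 120 trials —
enough for the Occam penalty to point at the null — and 5 effect
replicates at 24 participants × 200 trials per age, because a $+1.0$
log-unit asymptote effect is genuinely not identifiable much below that
size: at 4 per cell the posterior for the arousal coefficient spans
roughly $\pm 1.5$, and the Bayes factor then *correctly* favours the
null. BF-calibration simulations set the at-chance fraction to zero so
that comparison behaviour is measured on a fixed participant count;
screening calibration is tested separately with 10,000 simulated chance
responders.

## Known limitations

* Static HMC with jittered trajectory lengths mixes the weakly identified
  per-participant rate offsets slowly; budget draws accordingly or check
  `fit$diagnostics`.
* The normal bridge proposal can be draw-hungry beyond a few hundred
  parameters; warp bridges are a possible extension.
* One shared lapse (fixed or estimated) per model; no per-participant
  lapses.
* No alternative psychometric families (logistic, Gumbel) and no adaptive
  staircase support — the design this package targets uses fixed SOA
  sampling.
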