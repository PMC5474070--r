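---
title: "Multilevel EWA models of social learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel EWA models of social learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ewalearn)
```

This vignette is the package's account of the science it implements: the
learning model and its assumptions, the parameters and their defaults, what
the synthetic-data generator does and does not emulate, the numerical and
design choices that were genuinely open, and the known limitations.

## The model

### Individual learning

Experience-weighted attraction (EWA) models represent accumulated
experience as attraction scores $A_{ij,t}$, one per technique $i$ and
individual $j$. After each bout the performed technique's attraction moves
toward the realized pay-off $\pi$:

$$A_{ij,t+1} = (1-\phi_j)\,A_{ij,t} + \phi_j\,\pi_{ij,t}.$$

$\phi_j \in (0,1)$ is the updating (or "attraction to recent experience")
rate: small $\phi$ means canalized behaviour dominated by old experience.
The pay-off of a successful opening is the inverse log of the handling time,
$\pi = 1/\log T_\mathrm{open}$, and 0 for a failure. This pay-off declines
in $T_\mathrm{open}$ with the steepest declines early, which matches how a
forager experiences the difference between a 30 s and a 120 s extraction
better than a linear rate would. Durations are clamped below at 2 s so the
log is positive; real handling times are far above the clamp.

Only the performed technique's attraction is updated; unperformed options
neither decay nor update. The update rule is defined per observation of the
performed behaviour, and decaying unperformed options would add a second
forgetting process the data could not separate from $\phi$ at these sample
sizes. Choice given attractions is multinomial-logistic,
$P(i) \propto \exp(\lambda A_{ij,t})$, with a single group-level
sensitivity $\lambda$ (the field analysis this package follows found no
individual variation in $\lambda$ worth modelling, and per-individual
$\lambda$ trades off pathologically with per-individual attraction scales).

### Social learning

Realized choice mixes the individual soft-max with a social term:

$$P(i) = (1-\gamma_j)\,P_\mathrm{ind}(i) + \gamma_j\, S_{ij,t},$$

with $\gamma_j \in (0,1)$ the weight on social cues. The social term is a
log-linear multinomial over the techniques the individual actually
witnessed within a moving window:

$$S_{ij,t} \propto N_{ij,t}^{\,f_j}\,
  \exp\!\Big(\sum_k \beta_{k,j}\,\kappa_{k,ij,t}\Big),$$

where $N_{ij,t}$ counts witnessed bouts of technique $i$ (the individual is
in the bout's audience), $f_j$ is the frequency-dependence exponent
($f > 1$ conformity, $f < 1$ anti-conformity, $f = 1$ copying in proportion
to occurrence), and the five cues $\kappa$ are: the demonstrator's pay-off
($1/\log T$, 0 on failure); alpha rank (0/1); shared matriline (0/1); age
similarity $(1+|\Delta\mathrm{age}|)^{-1}$; and the demonstrator's
standardized age. Techniques never witnessed get $S_i = 0$; if nothing was
witnessed the social term is undefined and choice falls back to the
individual component alone — an absent information set should not pull
choice toward uniformity.

The exact algebra of the social term is stated in the source analysis only
as "a multinomial probability expression with a log-linear component"; the
$N^f \exp(B)$ form used here is the one that reproduces its described
limits (frequency-proportional at $f=1$, conformist at $f>1$) and is the
standard choice in this model family.

Cue values from multiple witnessed demonstrations of the same technique are
aggregated by arithmetic mean. Frequency information already enters through
$N^f$; summing cues would double-count frequency and make $\beta$ and $f$
mutually unidentifiable by construction.

### The moving window

Social information available at a decision is the window of the previous 14
days (configurable; the sensitivity set is 7/14/21/28), **plus** bouts
earlier the same day: a bout exactly 14 days old is inside, 15 days old is
outside. An individual's own bouts never enter its social window — they are
individual experience, already in $A$. Estimating window width as a free
parameter is deliberately excluded (it fits poorly in this model family);
only fixed-width sensitivity analysis is provided.

### Age links and varying effects

$\phi_j$ and $\gamma_j$ are logistic transforms of a linear predictor:
per-individual intercepts (non-centered varying effects with a common SD)
plus an age slope. Ages are standardized within the group before entering
the links and the age-bias cue, so slope priors are scale-free; the
per-year slopes reported for wild capuchins (about $-0.11$ per year for
both $\phi$ and $\gamma$) correspond to roughly $-0.75$ per standardized
unit at a typical group age SD of ~7 years, which is the generator default.
$f_j$ varies on the log scale (preserving $f > 0$) and cue influences
$\beta$ on the identity scale. By default only $\phi$ and $\gamma$ carry
varying effects in fitted models: at desk-scale data (hundreds to a few
thousand bouts) per-individual $f_j$ and $\beta_j$ are weakly identified,
and their hierarchical SDs are dominated by their priors. They can be
switched on via `ewa_spec(varying = c("phi","gam","f","beta"))`.

## Priors and sampling

Priors are weakly informative: standard normal on cue influences,
link-scale intercepts and slopes; half-normal(1) on between-individual SDs;
normal(1, 1) on $\log\lambda$. These keep prior mass of $\phi$ and $\gamma$
away from the 0/1 boundaries (about 99% of prior mass inside (0.01, 0.99))
and make the models sceptical of large effects.

Sampling uses the package's adaptive random-walk Metropolis-within-Gibbs
sampler on the unconstrained parameterization. Two properties make this
practical. First, the bout likelihood factorizes over actors once the
window counts and cue means are precomputed (they depend only on the data),
so a proposal on one individual's varying effect re-evaluates only that
individual's bouts; population-level proposals re-evaluate everyone, in
compiled code. Second, proposal scales adapt toward a 0.44 acceptance rate
during warmup and are frozen afterwards, preserving detailed balance for
the kept draws. Convergence is monitored by split-Rhat per coordinate; fits
with any Rhat above 1.1 are flagged (`converged = FALSE`, plus a warning),
never silently returned. For the model sizes in this package (10–25
individuals, up to ~2000 bouts, 13–40 parameters) a few thousand sweeps
mix adequately; posterior-SD-sensitive quantities such as `p_waic` benefit
from the longer schedules used in the heavier tests.

## Model set and comparison

`canonical_specs()` builds the nine learning-strategy models: individual
learning only; unbiased frequency copying ($f = 1$, no cues);
frequency-dependent copying ($f$ free); five single-cue models (pay-off,
rank, kin, age-similarity, age-bias; each with $f = 1$); and the global
model (all cues, $f$ free, age effects on $\phi$ and $\gamma$). The exact
membership of the published nine-model set is in unpublished supplementary
material, so the set is reconstructed from the strategies the analysis
discusses and is fully configurable through `ewa_spec()`.

WAIC is computed from the pointwise log-likelihood matrix with the bout
choice as the pointwise unit: `lppd_i = log mean_s exp(ll_si)`,
`p_waic_i = var_s(ll_si)`, `waic = -2 (lppd - p_waic)`, standard error from
the pointwise contributions. Model weights are Akaike-style,
$w_m \propto \exp(-\Delta_m/2)$. No PSIS-LOO and no pairwise-difference SE
are provided.

## The synthetic-data generator

`simulate_group()` forward-simulates the platform experiment exactly as the
statistical model assumes data are generated — the same window tallies,
cue values, mixture choice rule and attraction updates, applied
sequentially. Defaults emulate the field study: a 25-individual group
(ages spread 1–24 years, four matrilines, the oldest individual alpha),
seven technique profiles with the published success proportions (0.38–0.89
among ever-successful techniques; two never-successful) and log-normal
handling times matched to the published medians (29–211 s), 75 experimental
days, Poisson bout counts averaging 19/day (~1437 bouts in total), and
audiences of 0–3 observers per bout (1–4 foragers at a platform).
Generating parameters default to the published posterior medians
($\lambda$ 20.97, $\phi$ 0.15, $\gamma$ 0.14, $f$ 0.38, $\beta_\mathrm{pay}$
1.02, ...). Failure durations use the success distribution scaled by 1.5
(no failure-duration data exist for never-successful techniques). An
optional per-individual technique availability mask represents physical
constraints (e.g. juveniles unable to perform the canine-opening
technique); it is off by default.

What the generator does **not** emulate: endogenous attention (who chooses
to watch whom — audiences are random), platform spatial structure,
demography, observer error, and irregular field schedules. Passing
recovery tests on simulated data therefore shows the estimator is correct
for the assumed generative process, not that the process is true of real
capuchins.

### Fixture regimes

`make_fixture()` provides frozen scenarios. Two are *regime* fixtures whose
free parameters were set by design analysis, not by the field posterior:

- **conformist** ($f = 3$, equal-pay-off techniques, $\gamma = 0.85$,
  $\sigma_\gamma = 0.3$): with individual learning holding $1-\gamma$ of
  the choice mass and equal pay-offs, the majority's long-run frequency is
  bounded near $0.5 + \gamma/2$ once attractions equalize, so conformist
  *fixation* — the phenomenon this regime exists to exhibit — requires
  near-obligate social learners. This is the classic strong-conformity
  setting of cultural-transmission theory.
- **payoff-biased** ($\beta_\mathrm{pay} = 2$, $f = 1$, $\gamma = 0.4$,
  pay-off-contrast technique set): enough social weight that the pay-off
  cue materially steers choice; at the field-posterior $\gamma \approx
  0.14$ the social channel is too weak for *any* strategy-identification
  method at desk scale.
- **individual-only** ($\gamma = 0$) uses equal-pay-off techniques: with
  strong pay-off contrast, independent learners all converge on the best
  technique and the group's history becomes a proxy for each individual's
  own attractions (the equifinality problem that observational learning
  studies face); equal pay-offs make agents lock onto idiosyncratic
  techniques, so "no social learning" is actually distinguishable.
- **table1-like** is the full field-scale scenario at the published
  technique profiles and posterior-median parameters; **tiny** is a fast
  4-individual scenario for unit tests.

## Numerical choices

- Soft-max and the social term are computed on the log scale with
  max-subtraction; probability vectors are exact convex combinations, so
  they sum to 1 to machine precision.
- Window tallies use exact integer day arithmetic; the half-open rule is
  `now_day - W <= day < now_day`, plus same-day earlier-sequence bouts.
- Bout tables must be sorted by `(day, seq)`; unsorted input is an error
  because silent re-sorting would corrupt the attraction dynamics.
- Initial attractions are 0 (naive individuals) unless a per-individual
  matrix is supplied to represent experienced immigrants.
- The likelihood has a compiled fast path; an independent naive replay
  built from the exported single-step primitives lives in the test suite
  and agrees with the fast path to $10^{-10}$ on every fixture.
- Degenerate inputs: empty bout tables give zero log-likelihood; empty
  windows give no social term; a zero-variance pointwise matrix gives
  `p_waic = 0`.

## Problem sizes used in the heavy tests

Replicate studies run at sizes chosen for desk-scale property testing: the
recovery study uses 12 agents, 4 techniques and ~2000 bouts with 2 chains
× 1000 sweeps; strategy-identifiability replicates use the regime fixtures
at ~900 bouts with single 1000-sweep chains; window-sensitivity fits use
the single-cue pay-off model. These sizes are stated here as the package's
own experimental design.

## Known limitations

- $\beta_\mathrm{pay}$ is weakly identified at realistic social weights
  ($\gamma \approx 0.15$) and desk-scale data: its posterior SD remains
  near 1 (the prior SD) even with well-mixed chains — consistent with the
  published field posterior (median 1.02, SD 0.84). Sign recovery is
  reliable; interval exclusion of zero is not. The conformity exponent and
  the pay-off bias are partially confounded whenever the high-pay-off
  technique is also the majority, which is exactly what pay-off-biased
  diffusion produces.
- The random-walk sampler needs longer chains than a Hamiltonian sampler
  would for SD-sensitive summaries; Rhat flags, not divergence counts, are
  the convergence diagnostic.
- WAIC separates nested learning strategies only to within a few points at
  ~10^3 bouts; strategy identification is reported as a rate over
  replicates, never from a single dataset.
- The varying-effects structure is independent per parameter (no
  correlation matrix across $\phi$, $\gamma$, ...); the published analysis
  may have used a richer structure whose exact inventory is not
  reconstructable.
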