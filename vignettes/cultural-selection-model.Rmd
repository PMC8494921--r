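---
title: "The cultsel model: payoff-biased selection with uncritical defaults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cultsel model: payoff-biased selection with uncritical defaults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultsel)
```

## The model and its assumptions

`cultsel` simulates Darwinian cultural evolution as a discrete-time
stochastic process on a population of `N` agents. Each agent holds exactly
one cultural variant — an id into a fixed pool of `V` possible variants —
with no memory of earlier variants. The pool is the model's notion of
"everything this culture could invent": innovation and production error
both sample from it, so nothing outside the pool can ever arise. Variant
payoffs are objective properties of the pool, identical for every agent,
fixed for the whole run, and regenerated afresh for every run.

An agent update has three ingredients:

1. **Critical (payoff-biased) choice**, taken with probability `b`: the
   agent assembles three candidates — its own variant (payoff $p_s$), the
   variant of a randomly selected model ($p_m$), and a freshly innovated
   variant ($p_n$) — and adopts candidate $i$ with probability
   $p_i / (p_s + p_m + p_n)$ (roulette-wheel selection). If two candidates
   happen to carry the same variant id they keep separate roulette slots,
   so their masses add; that is the only reading under which the
   proportional rule stays total.
2. **Uncritical default**, taken otherwise: the learner type decides
   outright, without inspecting any payoff. Copiers adopt a model's
   variant, innovators draw a fresh one, maintainers keep their own.
   Learner type is homogeneous within a population.
3. **Production error**: with probability `e` the adopted variant is
   replaced by a uniform draw from the full pool (possibly the variant the
   agent was trying to produce).

Updates within a time step are *sequential*: agents update one at a time
and each update sees the current holdings of all other agents, so a later
agent can copy a variant an earlier agent adopted moments before. By
default the order is the fixed index order `0..N-1` every step — the
simplest scheme consistent with sequential updating, and the one that
makes small examples traceable by hand (with two error-free copiers, both
agents end the first step holding agent 1's initial variant). Setting
`shuffle_order = TRUE` re-randomises the order each step; in the sweeps we
have run this changes nothing qualitative.

Candidate draws are *lazy*: only the branch actually taken consumes random
numbers (the critical branch draws a model and an innovation; an
uncritical copier draws only a model; a maintainer draws nothing). This is
observationally equivalent to drawing everything eagerly and keeps the
random stream short and interpretable.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `payoff_bias` (b) | probability an update is critical | — | the swept quantity; study levels 0, 0.2, …, 1 |
| `learner_type` (t) | uncritical default strategy | — | the compared treatments |
| `error_rate` (e) | production-error probability | 0.02 | the rate used in transmission-chain experiments and prior models |
| `pool_size` (V) | number of possible variants | 100 | study value; population sizes are "large" or "small" only relative to it |
| `payoff_rate` (λ) | exponential rate of raw payoffs | 1 | study value; payoff = round(2x²)+1, so minimum 1, pool maximum typically ≈ 50 |
| `population_size` (N) | number of agents | — | study levels 10, 20, 100, 200 |
| `structure_sigma` (σ) | Gaussian offset sd on the ring; `NULL` = unstructured | `NULL` | study levels 1, 3, 5, 7 at N = 200 |
| `n_steps` | time steps per run | 200 | study value |

Payoffs are unitless scores; time is in agent-update rounds.

## Structured populations

With `structure_sigma` set, agents sit at unit spacing on a circular line
(agent 0 and agent N−1 are neighbours). A model is picked by drawing a
continuous offset from a zero-mean Gaussian with sd σ, rounding it to the
nearest integer (half away from zero) and wrapping around the ring. Zero
offsets are redrawn — rejection is the minimal implementation of "an agent
cannot be its own model" — as is the measure-zero case of an offset that
wraps exactly back onto the focal agent; a retry cap turns pathological
parameter choices into a hard error instead of a hang. The discretisation
is not uniquely determined by a verbal description of Gaussian
neighbourhoods; nearest-integer rounding is the natural choice and
reproduces the reference effective neighbourhood sizes: over a 200-draw
window on a 200-agent ring, `estimate_neighbourhood_size()` gives ≈ 5.9,
15.8, 24.8 and 33.0 distinct models for σ = 1, 3, 5, 7. Offsets beyond
the ring's half-length are neither truncated nor folded specially — plain
modular wrap-around — which is numerically irrelevant for σ ≤ 7 on
N = 200.

## Metrics

Diversity is the plain Gini-Simpson index $1 - \sum_v \hat p_v^2$ over
variant frequencies; its maximum for an N-agent population is exactly
$1 - 1/N$ (0.9, 0.95, 0.99, 0.995 for N = 10, 20, 100, 200), which is why
the uncorrected form is used rather than the unbiased finite-sample
estimator. Adaptation is the arithmetic mean payoff of the agents'
current variants. Both are recorded after every time step, plus a
`t = 0` baseline so trajectories start at their near-maximal initial
diversity.

## Randomness and reproducibility

A run consumes a single RNG stream seeded from `config$seed`, in a fixed
documented order (pool, initial variants, then per-agent draws). The
compiled engine and the pure-R reference engine
(`update_agent()`/`run_time_step()`) call the identical primitives in the
identical order, so `run_simulation(cfg, engine = "r")` is bit-identical
to the default compiled path — a strong regression guard, checked in the
test suite. Uniform index draws are `floor(u * n)` in both languages
(rather than R's `sample()`, whose internal algorithm the C side cannot
reproduce).

Sweeps derive one seed per (cell, replicate) through three rounds of the
MINSTD linear congruential generator mixing `(base_seed, cell,
replicate)`; the arithmetic is exact in doubles and the result is always a
valid 32-bit seed. Consequently any cell — or any single replicate — can
be re-run in isolation and reproduces the full sweep's numbers exactly,
and cell results are independent of execution order.

## What the simulations emulate, and what they do not

The generator *is* the study system: all inputs are parameters, and the
default grids (`build_sweep("size")`, `build_sweep("structure")`) are the
72-cell study conditions. What passing tests demonstrate is therefore
internal: that the engine implements this model exactly and that the
model, at these parameters, produces the documented population-level
patterns. Real cultural transmission differs in ways the model
deliberately idealises away: payoffs are objective and noiseless, learner
type never varies within a population, agents have no memory, evaluation
and learning carry no cost (a cost model would plug in naturally between
candidate assembly and the roulette — `candidate_set()` returns the
payoff column that such a modifier would transform before
`critical_choice()` — but none is implemented), and the variant space is
finite and static.

## Numerical and design choices

* **Rounding** is half-away-from-zero everywhere a continuous value
  becomes an integer (payoff transform, ring offsets); base R's `round()`
  rounds half to even, which is the wrong convention here (ties have
  probability zero, but the convention is stated for definiteness).
* **Roulette ties**: the cumulative-sum comparison is strict (`u <
  cum`), identical in both engines.
* **Degenerate inputs**: a single-variant pool is legal (everything
  collapses to variant 0); `n_steps = 0` yields only the baseline record;
  populations need at least 2 agents so a model always exists.
* **Replicate scale**: the full study runs 10,000 replicates per cell.
  The package defaults `build_sweep(n_replicates = 10000)` accordingly,
  but the test suite and examples run 200–1000 replicates per cell —
  enough to separate the learner types' confidence intervals at the
  parameter settings where the substantive claims live, while keeping a
  full check run in tens of seconds on one CPU.
* **Payoff bias plateau**: mean final payoff for maintainers rises
  steeply over b ∈ [0, 0.4] and then plateaus; at N = 10 the b = 1 level
  sits, if anything, marginally below b = 0.8, because a little
  uncritical maintenance skips risky roulette draws at no cost once the
  population already holds good variants. Ordering checks across b
  therefore compare successive replicate means with a sampling-error
  allowance instead of asserting strict monotonicity of noisy means.

## Known limitations

* The compiled engine does not accept R callbacks, so custom model
  selectors or payoff modifiers require the (slower) reference engine.
* Only two topologies exist: fully unstructured, and the Gaussian ring.
* Standard errors are stored per time step, but no formal
  hypothesis-testing machinery is included beyond what the tests
  themselves compute.
* Mean payoff trajectories depend on each run's random pool, so absolute
  payoff levels are comparable only across replicates (which is why all
  summaries average over many runs).
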