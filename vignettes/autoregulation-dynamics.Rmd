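---
title: "Boolean threshold networks: stability, robustness and the evolution of autoregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean threshold networks: stability, robustness and the evolution of autoregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolgrn)
```

## The model

An organism is a gene regulatory network of `N` genes. Its phenotype at
developmental time `t` is a vector `S(t)` with entries `s_i(t) ∈ {-1, +1}`
(gene off/on). Regulation is a signed integer matrix `W`: `w_ij` is the
effect of gene `j`'s product on gene `i`, with `w_ij ∈ {-1, +1}` for dense
networks and `{-1, 0, +1}` for sparse ones. Development iterates the
synchronous threshold update

```
s_i(t+1) = sgn( Σ_j w_ij s_j(t) ),    sgn(0) = +1
```

until the trajectory revisits a state. The segment between the two visits
is the *attractor*: a fixed point (length 1, a stable mature phenotype) or
a limit cycle. The state space is finite (`2^N` states) and the map is
deterministic, so an attractor is always reached; a cap of `2^N + 1`
examined states guarantees detection by pigeonhole. We default to exactly
that bound — whether the original implementation capped development
earlier is unknowable from the text, and the exact bound is cheap at
`N = 10` (1024 states).

All arithmetic is integer-exact. States are encoded canonically as bit
patterns, so revisit detection is exact equality, never a tolerance.

Throughout, the default network size is `N = 10` and the diagonal `w_ii`
is *autoregulation*. Three sign statistics summarise a network:

* `p` — fraction of positive diagonal entries (*sign of autoregulation*),
* `q` — fraction of positive off-diagonal entries,
* `r` — fraction of strictly positive entries in the strict upper
  triangle of `W Wᵀ`, a length-two indirect-autoregulation statistic.

`p`, `q`, `r` are exact rationals with denominators `N`, `N(N-1)` and
`N(N-1)/2`. For sparse networks the `p`/`q` denominators are the non-zero
entry counts (a sign fraction is undefined on structural zeros). Note that
the field motivates `r` through reciprocal activation loops, but its
printed definition is via `W Wᵀ` (shared-target correlation, which also
includes diagonal terms in the dot products); we implement the `W Wᵀ`
definition as printed. Zero dot products — possible at even `N` — count as
not positive, a literal reading of "number of positive elements".

## Stability, viability, robustness

A `(W, S0)` pair is *stable* if development reaches a fixed point;
*population stability* is the stable fraction of a population. A
*single-mutant scan* flips the sign of each of the `N²` entries in turn
(non-zero entries only, for sparse networks) and re-develops from the same
initial state:

* *viability* = fraction of mutants still reaching a fixed point;
* *robustness* = fraction of *viable* mutants reaching the *identical*
  fixed point as the unmutated network.

Robustness is undefined (reported `NA`, never 0) when no mutant is viable,
and undefined scans are excluded from population averages rather than
imputed — normalising by the viable count rather than `N²` is intended to
decouple stability from robustness. Scan tables additionally report the
unconditional preserved-phenotype fraction `n_same / N²`
(`fraction_same`); see "Known limitations" for why both matter.

## Generators

* `random_network()` — each entry ±1 with probability ½; `random_state()`
  likewise. The RNRC setup pairs each network with its own random state
  (non-evolving samples); RNIC gives all networks of a population one
  shared random state (evolving populations).
* `network_with_sign_composition(N, p, q)` — places *exactly*
  `round(p·N)` positive diagonal and `round(q·N(N-1))` positive
  off-diagonal entries at uniform positions. Exact counts, not
  Bernoulli draws: the analyses bin by the 11 discrete values of `p` at
  `N = 10`, and exact placement removes binning noise. Off-grid `p`/`q`
  are errors rather than silently rounded.
* `stable_network()` — rejection-samples `(W, S0)` pairs until a fixed
  point is reached (default cap 10⁶ draws; at `N = 10` the acceptance
  probability is far above the cap's reciprocal for every `p` bin, and
  exceeding the cap raises an error rather than looping forever).
* `sparse_regular_network(N, degree)` — superposes `degree` random
  permutation matrices, rejecting collisions, so in-degree = out-degree =
  `degree` exactly; density `c = degree/N` (`0.2` at the defaults).
  Self-loops are allowed by default: the diagonal analyses need
  autoregulatory entries to exist. The published construction is not
  described; regular superposed permutations are the canonical way to get
  an exact-degree directed graph.
* `engineered_network(donor, diag_p)` — off-diagonal entries of a stable
  low-`p` donor plus a fresh high-`p` diagonal. Donors are harvested by
  rejection at exact composition `p = 0.1`, `q = 48/90 ≈ 0.533` (the grid
  value nearest the reported equilibrium 0.53–0.54; the source gives
  target values, not a harvesting procedure).

## Evolution

`evolve()` runs `z` independent RNIC populations of `n = 500` networks
through Wright–Fisher generations:

1. develop every organism from the population's *fixed founding state*
   (the same state every generation),
2. fitness under the selection model,
3. resample `n` organisms with replacement, probability ∝ fitness,
4. optional recombination: shuffle into `n/2` disjoint pairs; each pair's
   offspring take complementary random halves of the *rows* (full-row
   segregation, no crossover within rows),
5. mutation: each entry flips sign independently with probability
   `μ/N²` (`μ = 0.1` ⇒ 0.001 per entry, 0.1 flips per network per
   generation); sparse entries flip at `μ/(cN²)` and zeros never change.

The operator order and the disjoint pairing are design choices — the
source states the mechanisms but not their order; we follow the Wagner
lineage the mechanisms cite. Fitness uses the exponential form
`exp(-d/σ)` in the normalized Hamming distance `d` to the target, which
matches both printed limits (`σ = 0.1` strong selection; `σ = ∞` erases
fitness differences). The four selection regimes:

| model | selects | fitness |
|---|---|---|
| 1 "target" (`σ = 0.1`) | a specific fixed point | `exp(-d/σ)` if `l = 1`, else 0 |
| 1 "no target" (`σ = ∞`) | any fixed point | 1 if `l = 1`, else 0 |
| 2 (`l_opt ∈ 2..7`) | cycles of one length | 1 iff `l = l_opt` (fixed points excluded) |
| 3 (`σ = 0.1`, target) | best state of any attractor | `max exp(-d/σ)` over the cycle |
| 4 | nothing (drift) | 1 |

With `σ = ∞` the fixed-point fitness is *exactly* 1 (integer Hamming
distance over `Inf` is exactly 0), so under "no target" mean fitness
equals stability identically — a useful engine invariant that the tests
assert. If every organism has fitness 0 (possible early under model 2),
the population is resampled uniformly rather than going extinct, and the
event is counted in `rescue_events`.

Reproducibility: population `k` of a run re-seeds R's RNG with
`seed + k - 1`, so sets are bit-reproducible and insensitive to execution
order. The per-generation metrics (`p`, `q`, stability, mean fitness) are
recorded every generation; `r`, the mutant scans and the
interaction-strength matrix `o_ij` only at `scan_schedule` generations
(default ~20 log-spaced points), because `N²` mutant developments per
organism dominate the cost and the published time courses are smoothed
anyway.

Conservation of a matrix element between two recorded generations is
defined here as the same-sign-draw probability
`o₁o₂ + (1-o₁)(1-o₂)` — the chance that a network drawn at `t₁` and one
drawn at `t₂` agree in sign at that position. The printed expression for
this statistic did not survive into the extracted source (a placeholder
containing `abs`), so this is a definition choice, flagged as such: it
yields 0.5 at the independence baseline and 1 for frozen signs, and
reproduces the qualitative contrasts (diagonal more conserved than
off-diagonal under stability selection; less conserved under drift), but
published conservation *medians* (0.86/0.70/0.68) need not transfer.

## What the experiments compute

* `run_stability_vs_p()` — RNRC sampling across `p = 0, 0.1, …, 1`;
  stability per bin and the `p` medians of the stable/unstable classes
  (≈ 0.9 vs ≈ 0.4 at `10⁴` networks per bin).
* `run_timecourse()` — trajectory of the set means. Under "no target",
  `p` rises above 0.9 within ~50 generations (stability ≈ 0.96 at the
  peak), then relaxes to ≈ 0.8; `q` peaks in the 0.6–0.7 range around
  generation ~500 before declining. Under cycle selection (`l_opt = 2`)
  `p` falls to ~0.2–0.3; under drift it stays at 0.5.
* `run_mutant_position_analysis()` — per-element mutant stability of
  evolved stable networks: overall viability high (~0.95–0.98 at the
  scaled horizon), diagonal mutants least viable.
* `run_conservation_analysis()` — diagonal vs off-diagonal conservation
  between two recorded generations, stability selection vs drift.
* `run_engineered_comparison()` — engineered networks vs
  composition-matched random stable controls: higher robustness and
  higher `r`.

## Problem sizes

The published experiments use `z` up to 300 populations and `10⁶–10⁷`
generations (~`10⁵` networks per generation). This package's default
recipes are scaled down to `z = 20` populations, `10⁴` generations and
`10³–10⁴` networks per bin — the regime where the time courses have
reached (or nearly reached) their equilibria per the published phase
description (`p` equilibrates from ~`10³`; robustness and `q` continue
drifting slowly to ~`10⁵`). Consequences of the shorter horizon we
observe: end-of-run viability sits slightly above the published
equilibrium value (≈ 0.97 vs 95%), and the raw per-generation set-mean
`q` peak (~0.67 at `z = 20`) reads higher than the smoothed published
curve (~0.63). Both gaps shrink with `z` and run length.

## The synthetic-data generators emulate, and what tests show

All experiment inputs are generated internally: there is no external
data. The generators emulate the study's *in silico* conditions exactly
(binary signed matrices, uniform random states, exact-composition bins),
not real gene networks: real regulatory networks are sparse,
scale-free-ish, have graded kinetics and asynchronous timing, and their
"initial conditions" are not uniform draws. Passing tests therefore
validate the model reconstruction and its statistics — not claims about
any particular biological network. The biological reach of the model is
the original study's argument, not something these simulations can
re-establish.

## Numerical choices and degenerate inputs

* `sgn(0) = +1` exactly as specified; with even in-degree, ties at 0 are
  common and materially affect the dynamics, so the convention is load-
  bearing, not cosmetic.
* Weighted sums, Hamming counts and sign counts are integers; the only
  floating-point quantities are fitnesses and averaged metrics.
* Compiled batch dynamics require `N ≤ 20` (bit-packed states with a
  `2^N` visit table); `find_attractor()` itself accepts `N ≤ 31`. The
  study regime is `N = 10`.
* Degenerate cases: empty populations error; all-zero-fitness
  populations rescue uniformly; `p`/`q` on an all-zero diagonal or
  off-diagonal are `NA` with a warning; off-grid compositions error;
  mutant scans of unstable originals error (robustness is only defined
  for stable wild types).

## Known limitations

* **Robustness normalisation.** With robustness defined as
  `n_same/n_fixed` (the printed definition), mean robustness of stable
  non-evolved `q = 0.5` networks *decreases* from ~1.0 at `p = 0` to
  ~0.57 at `p = 1` in this reconstruction: the rare low-`p` stable
  networks owe their stability to large off-diagonal majorities, so the
  few viable mutants almost never change the fixed point, while `p = 1`
  networks sit near `sgn(0)` ties. The published claim that non-evolved
  robustness is maximised at `p = 1` — and the observation that evolved
  networks are about twice as robust as composition-matched non-evolved
  ones — are reproduced here only by the unconditional fraction
  `n_same/N²` (≈ 0.35 → 0.49 across bins). Scan tables therefore carry
  both quantities, and conclusions that depend on the choice are flagged
  where they arise.
* Conservation medians depend on the unrecoverable printed formula (see
  above).
* Asynchronous updates, real-valued states, scale-free topologies and
  multistability analyses are out of scope.
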