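---
title: "Evolution as a walk through a graph of games: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution as a walk through a graph of games: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nashevol)
```

## The model

`nashevol` models a haploid population with `m` loci. At any moment only a
finite set of alleles is available at each locus; that profile of sets is
the *allelic formation*, and a *genotype* is one allele per locus. Each
genotype `g` carries a fixed, strictly positive fitness `w_g` (no frequency
dependence). Treating the loci as players whose actions are their alleles
and whose common payoff is the genotype's fitness yields a
*common-interests game*: mean population fitness is then a potential
function shared by all players.

Two deterministic flows act between mutations:

* **Asexual (genotypic) replicator.** The state is a distribution `p` over
  genotypes and `dp_g/dt = p_g (w_g - w(p))` with `w(p) = sum_g w_g p_g`.
  From any interior start the flow ascends `w` and fixes the fittest
  genotype present.
* **Sexual (allelic) multi-replicator.** Under full recombination and no
  cross-locus correlation, the state is one frequency vector per locus
  (a point of the multi-simplex) and each allele grows at its marginal
  fitness excess: `dq^i_j/dt = q^i_j (w^i_j(q) - w(q))`, where the
  marginal `w^i_j` is the mean fitness of genotypes carrying allele `j` at
  locus `i` under the product distribution of the other loci. This flow is
  gradient ascent of `w(q)` in the Shahshahani metric (coordinate `(i,j)`
  weighted by `1/q^i_j`); from interior starts it converges to a
  monomorphic state whose genotype is a *strict pure Nash equilibrium* of
  the game — a local fitness peak under single-allele substitutions.

Mutations arrive on a Poisson clock with rate `lambda`; each event draws a
locus uniformly and an allele uniformly from that locus's *universe pool*.
A *non-novel* event re-proposes a present allele and changes nothing. A
*novel* event expands the game by one action (*game-changing*); if the
expansion removes the occupied equilibrium from the pure Nash set it is
*Nash-changing*, and the population must travel to a new, strictly fitter
equilibrium. Evolution is thus a piecewise-deterministic Markov process
over a growing graph of games, and the sequence of occupied-equilibrium
fitness values is weakly increasing, stepping up exactly at Nash-changing
events.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `delta` | 1/4 | fitness of the deleterious intermediates in the worked 2-locus landscapes; any value in (0,1) preserves their equilibrium structure, and the fixtures expose it rather than fixing it |
| `eps` (worked initial state) | 0.01 | trace weight on the one-step neighbours of the resident genotype; small enough to sit deep in the resident basin, large enough for fast relaxation |
| `eps_mut` | 1e-3 | frequency at which a novel allele is injected. The replicator cannot grow an allele from exactly 0, so a strictly positive injection is mandatory; 1e-3 is small enough not to bias basin outcomes in any fixture |
| `lambda` | per study | Poisson clock rate, in units of inverse flow time. The jump-chain reading assumes `1/lambda` exceeds the relaxation time (typically 10–10^3 time units here) |
| `tol_v`, `tol_m` | 1e-9, 1e-6 | stopping tolerances: velocity max-norm, and leading mass per simplex block |
| `horizon` | 1e4 | integration-time cap; property studies over random games raise it to 1e6 because near-ties in fitness make relaxation times of order `1/gap` |

## Numerical design

**Log-coordinate integration.** The flows are integrated by an adaptive
Dormand–Prince 4(5) scheme (relative tolerance 1e-8) written in C++, in
log-frequency coordinates: with `u = log q`, the multi-replicator becomes
`du^i_j/dt = w^i_j(q(u))` up to a per-block shift removed by softmax
normalization — a bounded, smooth field. This choice is load-bearing. The
valley-crossing trajectory suppresses an allele to frequencies of order
1e-80 before it returns and sweeps; any integrator controlling *absolute*
error freezes such coordinates and converges to the wrong vertex. In log
coordinates accuracy is uniformly *relative*, exact zeros stay exact
(`u = -Inf` is invariant, matching the replicator's face invariance), and
the asexual flow is integrated essentially exactly (its log-field is
constant). The test suite cross-checks trajectories against a
general-purpose ODE solver on the R-side field and against the asexual
closed form `p(t) ∝ p(0) e^{wt}`.

**Stopping and attribution.** Integration stops when the frequency
velocity max-norm falls below `tol_v` or every simplex block concentrates
mass above `1 - tol_m` — but a stop is only accepted if the modal vertex is
a genuine attractor (strict pure Nash for the sexual flow; fitness-maximal
within the positive support for the asexual flow). Near an unstable vertex
both criteria fire spuriously while an escape direction still carries
astronomically small mass; the guard keeps the integrator on the trajectory
until it reaches a true attractor or the horizon. Converged sexual runs are
attributed to the nearest strict Nash vertex in L1 distance (summed over
loci; the distance `distance_to_nash()` uses the same convention).

**Degenerate inputs.** Boundary states are allowed (faces are invariant);
interiority is flagged because the Nash-convergence guarantee needs it.
Weak (tied) equilibria occur in the 3×3 worked landscape, where
`w(a1,b3) = w(a2,b3)`; `pure_nash(strict = FALSE)` computes the weak set,
while the dynamics and classification default to strict equilibria, the
generic monomorphic limits.

## The mutation process: two readings

`run_pdmp()` exposes both readings of the inter-event flow:

* `relax = "converge"` (default): each segment relaxes to equilibrium
  before the next event applies — the rare-mutation *jump chain*. In this
  regime the recorded equilibrium snapshots are exactly the chain the
  theory describes: weakly increasing fitness, strict increase exactly at
  Nash-changing events, non-novel events exactly neutral.
* `relax = "wait"`: segments run for exactly the sampled exponential
  waiting times — the true finite-rate process. Mid-transit segments
  attribute their occupied equilibrium by the *basin limit* (a continuation
  integration from the segment-end state). When events arrive faster than
  the flow relaxes, the jump-chain invariants can genuinely fail — that is
  a property of the model, not an artifact — so the monotonicity checks are
  run in the jump-chain regime and the near-equilibrium-residence check
  (below) in the finite-rate regime.

In both readings the *actual segment-end state* (not an idealized vertex)
is embedded when a novel allele arrives, so the process stays well defined
at any rate.

## The centered fitness walk

Let `Y_k` be the equilibrium fitness established by the `k`-th novel
mutation, read through the deterministic continuation map (embed the
allele, integrate to convergence) — the rare-mutation reading of the
pre-arrival fitness. The centered walk

```
Z_k = Z_{k-1} + Y_k - E[Y_k | history],    Z_0 = 0
```

is a martingale: it retains only the unpredictable part of each fitness
jump. With `sigma_k^2` the conditional variance of the `k`-th increment,
the walk is read off at `kappa_v`, the first index where the accumulated
conditional variance reaches a budget `v`, and `F = Z_{kappa_v} / sqrt(v)`
is asymptotically standard normal as `v` grows. Conditional moments are
estimated by replaying sibling continuations from the frozen pre-event
state: a branching Monte Carlo sample (`estimator = "branching"`, `B = 20`
siblings by default), or exact enumeration of the finite candidate pool
with its sampling weights (`estimator = "exact"`), which the package uses
whenever pools are small. Because the realized next equilibrium is
recomputed through the same continuation map as the siblings, the
exact-estimator increments are exactly conditionally centered, whatever
`lambda` is. Runs whose total accumulated variance never reaches `v` are
excluded with a warning, and `F` inherits a small upward variance bias from
the overshoot of the budget at the stopping index (`Var(F) = 1 +
E[overshoot]/v`), which the study design keeps small.

## What the synthetic generators emulate

* `random_game()` draws i.i.d. fitness from a continuous positive law
  (Uniform(0.5, 2.5)), giving *generic* landscapes: all values distinct,
  a unique global optimum, strict equilibria only. It emulates rugged
  epistatic landscapes with no structure; near-ties arise by chance and
  make relaxation slow, which is why property studies extend the horizon.
* `additive_universe()` builds a no-epistasis master landscape: fitness is
  the sum of per-locus allele effects (wild type 1, novel effects
  Uniform(1, 1.5)). Every locus sweeps independently, so the mutation
  process yields a sustained stream of modest, independent fitness jumps —
  the regime in which the centered walk accumulates variance in many small
  steps. The walk study uses 4 loci with pools of 5, `v = 0.07`, the exact
  estimator, and 600 runs: the budget is far below the total variance a
  run accumulates (so `kappa_v` is essentially always reached) while large
  relative to single steps near the stopping index (keeping the overshoot
  bias in `Var(F)` a few percent).

Neither generator models linkage, drift, finite populations, allele loss,
or frequency-dependent fitness; passing tests certify the mean-field model
on these landscape classes, not those phenomena.

## Problem sizes used by the checks

The worked-example checks integrate 2×2 to 3×3 games (milliseconds each).
The structural property studies use: 1000 random interior points for the
Shahshahani residual (central differences, `h = 1e-5`, residual below
1e-6); 20 random generic games × 100 interior starts per mode for the
convergence/ascent properties (horizon 1e6); 50 seeded jump-chain runs for
path monotonicity; one 200-event finite-rate run at `lambda = 0.01` for
near-equilibrium residence (distance below 0.05 in the last 5% of more
than 95% of inter-arrival intervals); and the 600-run walk ensemble above,
checking the sample mean of `F` within ±0.1 and variance within
[0.7, 1.3].

## Known limitations

* Attribution of an occupied equilibrium is by basin limit / nearest
  strict Nash; games with only weak equilibria (ties at the top) have no
  strict attractor and integration then runs to the horizon.
* Convergence-time, not correctness, is the binding constraint on random
  landscapes: a fitness gap `g` costs time of order `log(1/eps)/g`.
* The event sampler's uniform locus/allele law is one simple exchangeable
  choice; it is isolated behind `sample_next_event()` so other laws can be
  substituted.
* The walk's conditional moments are exact only under the exact
  enumeration estimator; branching estimates add `O(1/B)` variance.
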