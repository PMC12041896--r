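# nashevol

Evolutionary dynamics of haploid, sexually reproducing populations, modeled
as a common-interests game played by the loci: the alleles are the actions
and every locus receives the genotype's fitness `w_g` as its payoff.

**Who this is for.** Researchers in evolutionary game theory and population
genetics who want a tested simulator for multilocus haploid selection under
full recombination, for the mutation-driven expansion of the allele space,
and for the statistics that follow from it (fitness-valley crossing,
mutation-order contingency, arrival-order probabilities, and the
martingale-normalized fitness walk).

## The model in brief

Between mutations the population flows deterministically:

* asexual (genotypic) replicator: `dp_g/dt = p_g (w_g − w(p))`, which fixes
  the fittest genotype present;
* sexual (allelic) multi-replicator, one simplex per locus:
  `dq_j^i/dt = q_j^i (w_j^i(q) − w(q))`, where `w_j^i` is the allele's
  marginal fitness. This flow is Shahshahani-gradient ascent of mean
  fitness and converges from interior states to a monomorphic **strict pure
  Nash equilibrium** of the game — a local fitness peak under single-allele
  substitutions.

Novel mutations arrive as a Poisson process (rate `λ`), each adding one
allele to one locus and thereby **changing the game**. If the occupied
equilibrium survives the expansion, nothing happens in the long run; if it
is destroyed (a **Nash-changing** mutation), the population travels to a
new equilibrium of strictly higher fitness. The result is a
piecewise-deterministic Markov process over a growing graph of games whose
equilibrium fitness is weakly increasing — and a sexual population can
cross a fitness valley after a *single* mutation, where the classical
fixed-landscape picture requires at least two.

## A worked example

The classic two-locus valley: residents `(a1,b1)` at fitness 1, a better
peak `(a2,b2)` at fitness 2, deleterious intermediates at `δ = 1/4`. A
mutation introduces allele `b3` (the expanded game's extra column), which
destroys the `(a1,b1)` equilibrium:

```r
library(nashevol)

g1 <- example_matrix(1, delta = 0.25)   # 2x2 landscape
g2 <- example_matrix(2, delta = 0.25)   # + allele b3

p0 <- genotype_state(g1, c("a1,b1" = 0.99, "a2,b1" = 0.005,
                           "a1,b2" = 0.005, "a2,b2" = 0))
q0 <- allelic_state_of(g1, p0)          # per-locus frequencies
q1 <- embed_state(q0, g1$formation, "B", "b3", eps_mut = 1e-3)

tr <- integrate_to_equilibrium(g2, q1, mode = "sexual")
tr
#> sexual trajectory: 95 snapshots over [0, 535.6], converged (velocity)
#>   mean fitness 0.993071 -> 2; attributed limit a2,b2 (w = 2)
tr$final_state$B["b3"]
#>          b3
#> 6.867113e-10
```

The population crosses the valley to `(a2,b2)` (mean fitness 2) and the
triggering allele `b3` itself goes extinct — an observer comparing
before/after would see no trace of it. The mutation-order experiment shows
contingency: adding `b3` then `a3` versus `a3` then `b3` ends on different
peaks (fitness 2 vs 3):

```r
m4 <- example_matrix(4, 0.25)
cc <- compare_contingency(m4, g1$formation, q0,
  list(list(locus = "B", allele = "b3"), list(locus = "A", allele = "a3")),
  list(list(locus = "A", allele = "a3"), list(locus = "B", allele = "b3")))
cc$finals
#>       a       b
#> "a2,b2" "a3,b1"
cc$divergent
#> [1] TRUE
```

`run_pdmp()` simulates the full mutation process against an allele
universe, `find_fitness_valleys()` detects valley pairs,
`arrival_order_probability()` gives `λa/(λa+λb)` closed forms, and
`fitness_walk()` computes the centered fitness martingale and its
CLT-normalized endpoint. A thin CLI (`exec/nashevol`) wraps the same
functions (`nash`, `simulate`, `pdmp`, `valleys`, `contingency`,
`order-prob`, `example`, `randgame`).

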