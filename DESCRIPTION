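Package: nashevol
Title: Game-Changing Mutations and Replicator Dynamics in Haploid Sexual
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the evolution of haploid sexually reproducing populations
    as a common-interests game played by the loci, with alleles as actions and
    genotype fitness as the shared payoff. Between mutations the population
    flows deterministically: the asexual (genotypic) replicator ascends mean
    fitness to the fittest genotype, while the sexual (allelic)
    multi-replicator ascends mean fitness to a monomorphic pure Nash
    equilibrium of the game. Novel mutations arrive as a Poisson process and
    expand the game by adding an allele, yielding a piecewise-deterministic
    Markov process over a growing graph of games; events are classified as
    non-novel, game-changing, or Nash-changing (the previously occupied
    equilibrium is destroyed and mean fitness rises). Includes pure Nash
    enumeration, fitness-valley detection, mutation-order contingency
    analysis, arrival-order probabilities, and the centered fitness random
    walk with its martingale central-limit normalization, together with
    fixtures for the worked two-locus landscapes and random generic games.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
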