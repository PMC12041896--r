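#' The worked two-locus landscapes
#'
#' The four fitness matrices used throughout the package's worked examples,
#' on loci `A` and `B`. Matrix 1 is the 2x2 valley landscape (local optima
#' `(a1,b1)` with fitness 1 and `(a2,b2)` with fitness 2, off-diagonal
#' `delta`); Matrix 2 adds allele `b3` (with `w(a2,b3) = 7/4`), destroying
#' the `(a1,b1)` equilibrium; Matrix 3 instead adds `a3` (with
#' `w(a3,b1) = 3`); Matrix 4 contains both added alleles. The `(a1,b3)` cell
#' of Matrix 2 is not pinned down by the 2x2 story and is set to `3/2`,
#' matching its value in Matrix 4; note Matrix 4 carries `w(a2,b3) = 3/2`,
#' creating a weak (non-strict) equilibrium at `(a1,b3)`.
#'
#' @param n Which landscape, 1-4.
#' @param delta Off-diagonal fitness of the deleterious single-step
#'   intermediates, in (0, 1) (any value below 1 preserves the equilibrium
#'   pattern).
#' @return A `ci_game`.
#' @examples
#' pure_nash(example_matrix(1))
#' @export
example_matrix <- function(n, delta = 0.25) {
  if (!n %in% 1:4) stop("`n` must be 1, 2, 3 or 4")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1)
    stop("`delta` must lie strictly between 0 and 1")
  d <- delta
  fit <- switch(as.character(n),
    `1` = c("a1,b1" = 1, "a1,b2" = d,
            "a2,b1" = d, "a2,b2" = 2),
    `2` = c("a1,b1" = 1, "a1,b2" = d, "a1,b3" = 3 / 2,
            "a2,b1" = d, "a2,b2" = 2, "a2,b3" = 7 / 4),
    `3` = c("a1,b1" = 1, "a1,b2" = d,
            "a2,b1" = d, "a2,b2" = 2,
            "a3,b1" = 3, "a3,b2" = d),
    `4` = c("a1,b1" = 1, "a1,b2" = d, "a1,b3" = 3 / 2,
            "a2,b1" = d, "a2,b2" = 2, "a2,b3" = 3 / 2,
            "a3,b1" = 3, "a3,b2" = d, "a3,b3" = d))
  a <- if (n %in% c(3, 4)) c("a1", "a2", "a3") else c("a1", "a2")
  b <- if (n %in% c(2, 4)) c("b1", "b2", "b3") else c("b1", "b2")
  common_interests_game(allelic_formation(list(A = a, B = b)), fit)
}

# the examples' shared initial state: nearly monomorphic (a1,b1) with
# trace weight eps/2 on each deleterious one-step neighbour
example_initial_p <- function(game, eps = 0.01) {
  w <- numeric(length(game$fitness))
  names(w) <- names(game$fitness)
  w["a1,b1"] <- 1 - eps
  w["a2,b1"] <- eps / 2
  w["a1,b2"] <- eps / 2
  genotype_state(game, w)
}

#' Worked example scenarios
#'
#' Packages the three worked scenarios as replayable objects: a master
#' landscape (allele universe), the starting formation, the shared initial
#' state (`1 - eps` on `(a1,b1)`, `eps/2` on each of `(a2,b1)` and
#' `(a1,b2)`), a scripted mutation sequence, and the expected qualitative
#' outcome labels.
#'
#' * `valley_crossing`: adding `b3` destroys the occupied `(a1,b1)`
#'   equilibrium; the sexual flow crosses to `(a2,b2)` (with `b3` itself
#'   going extinct) while the asexual flow, which cannot recombine, fixes
#'   `(a1,b3)`.
#' * `blocked_sweep`: a non-novel mutation to the already-feasible
#'   `(a2,b2)` leaves the sexual population at `(a1,b1)`, but sweeps the
#'   asexual population to `(a2,b2)`.
#' * `contingency`: orders `b3` then `a3` versus `a3` then `b3` end at
#'   different equilibria (`(a2,b2)` vs `(a3,b1)`).
#'
#' @param name One of `"valley_crossing"`, `"blocked_sweep"`,
#'   `"contingency"`.
#' @param order For `"contingency"`: `"ab"` (add `b3` first, the default)
#'   or `"ba"` (add `a3` first).
#' @param delta,eps Landscape and initial-state parameters.
#' @return A `scenario` list with fields `name`, `universe`, `formation`,
#'   `initial_p`, `script` (list of `locus`/`allele` events; empty for
#'   non-novel scripts), `non_novel` (genotype of a scripted non-novel
#'   mutation, if any) and `expected` labels.
#' @seealso [replay_scenario()]
#' @export
example_scenario <- function(name = c("valley_crossing", "blocked_sweep",
                                      "contingency"),
                             order = c("ab", "ba"), delta = 0.25,
                             eps = 0.01) {
  name <- match.arg(name)
  order <- match.arg(order)
  m1 <- example_matrix(1, delta)
  sc <- switch(name,
    valley_crossing = list(
      universe = example_matrix(2, delta),
      script = list(list(locus = "B", allele = "b3")),
      non_novel = NULL,
      expected = list(sexual_final = "a2,b2", asexual_final = "a1,b3",
                      sexual_fitness = 2)),
    blocked_sweep = list(
      universe = example_matrix(1, delta),
      script = list(),
      non_novel = c("a2", "b2"),
      expected = list(sexual_final = "a1,b1", asexual_final = "a2,b2",
                      sexual_fitness = 1, asexual_fitness = 2)),
    contingency = list(
      universe = example_matrix(4, delta),
      script = if (order == "ab")
        list(list(locus = "B", allele = "b3"),
             list(locus = "A", allele = "a3"))
      else
        list(list(locus = "A", allele = "a3"),
             list(locus = "B", allele = "b3")),
      non_novel = NULL,
      expected = list(sexual_final = if (order == "ab") "a2,b2" else "a3,b1",
                      sexual_fitness = if (order == "ab") 2 else 3)))
  structure(c(list(name = name, order = order, delta = delta, eps = eps,
                   formation = m1$formation, initial_p = example_initial_p(m1, eps)),
              sc),
            class = "scenario")
}

#' Random generic common-interests game
#'
#' Fitness values drawn i.i.d. from a continuous positive law (default
#' Uniform(0.5, 2.5)), so all values are distinct with probability one and
#' the game is generic; on the measure-zero event of a tie the draw is
#' repeated. Uses the current RNG state — `set.seed()` first for
#' reproducibility.
#'
#' @param shape Integer vector of allele counts per locus (loci are named
#'   `L1, L2, ...` with alleles `L1.1, L1.2, ...` unless `loci`/prefixes are
#'   supplied via `formation`).
#' @param law Function `n -> n` positive draws.
#' @param formation Optional `allelic_formation` to use instead of `shape`.
#' @return A `ci_game`.
#' @export
random_game <- function(shape = c(2, 2),
                        law = function(n) stats::runif(n, 0.5, 2.5),
                        formation = NULL) {
  if (is.null(formation)) {
    if (any(shape < 1)) stop("all entries of `shape` must be >= 1")
    al <- lapply(seq_along(shape), function(i)
      paste0("L", i, ".", seq_len(shape[i])))
    names(al) <- paste0("L", seq_along(shape))
    formation <- allelic_formation(al)
  }
  ng <- prod(lengths(formation$alleles))
  for (try in 1:100) {
    w <- law(ng)
    if (any(w <= 0)) stop("`law` produced non-positive fitness")
    if (!anyDuplicated(w)) break
  }
  common_interests_game(formation, w)
}

#' Random interior state
#'
#' Dirichlet(1,...,1) draws per simplex: a uniform interior point of the
#' genotype simplex (`mode = "asexual"`) or of each per-locus simplex
#' (`mode = "sexual"`).
#'
#' @param game A `ci_game`.
#' @param mode `"sexual"` or `"asexual"`.
#' @return A state suitable for [integrate_to_equilibrium()].
#' @export
random_interior_state <- function(game, mode = c("sexual", "asexual")) {
  stop_if_not_game(game)
  mode <- match.arg(mode)
  rdir <- function(k) {
    x <- stats::rgamma(k, shape = 1)
    x / sum(x)
  }
  if (mode == "sexual") {
    q <- lapply(game$n_alleles, rdir)
    names(q) <- game$formation$loci
    allelic_state(game$formation, q)
  } else {
    genotype_state(game, rdir(length(game$fitness)))
  }
}

#' Synthetic no-epistasis allele universe
#'
#' A master landscape for studies of the long-run mutation process: fitness
#' is additive across loci, each allele contributing an independent effect
#' (wild-type effect 1, novel effects drawn from `effect_law`). Without
#' epistasis every locus sweeps independently, so the landscape supplies a
#' sustained stream of Nash-changing mutations of modest, independent
#' sizes — the regime in which the centered fitness walk accumulates
#' variance in many small steps. Uses the current RNG state.
#'
#' @param n_loci Number of loci.
#' @param pool_size Total alleles per locus in the universe pool (1
#'   wild-type + `pool_size - 1` novel candidates).
#' @param effect_law Function `n -> n` positive effects for novel alleles
#'   (default Uniform(1, 1.5)).
#' @return List with `universe` (a `ci_game` over the full pools),
#'   `formation` (the wild-type-only starting formation) and `effects`
#'   (per-locus effect vectors).
#' @export
additive_universe <- function(n_loci = 4, pool_size = 4,
                              effect_law = function(n) stats::runif(n, 1, 1.5)) {
  stopifnot(n_loci >= 1, pool_size >= 1)
  loci <- paste0("L", seq_len(n_loci))
  al <- lapply(loci, function(l)
    c(paste0(l, ".wt"), if (pool_size > 1)
      paste0(l, ".m", seq_len(pool_size - 1L))))
  names(al) <- loci
  f <- allelic_formation(al)
  effects <- lapply(seq_len(n_loci), function(i) {
    e <- c(1, effect_law(pool_size - 1L))
    names(e) <- al[[i]]
    e
  })
  names(effects) <- loci
  gm <- enumerate_genotypes(f)
  w <- numeric(nrow(gm))
  for (i in seq_len(n_loci)) w <- w + effects[[i]][gm[, i]]
  names(w) <- rownames(gm)
  start <- allelic_formation(lapply(al, function(a) a[1L]))
  list(universe = common_interests_game(f, w), formation = start,
       effects = effects)
}
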