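#' The graph of allelic formations
#'
#' Formations are arranged in a directed graph with an edge from `f1` to
#' `f2` exactly when `f2` adds a single new allele to a single locus of
#' `f1`. A novel mutation is one step along such an edge; a walk through the
#' graph is a novel-mutation process. The graph is never materialized —
#' edges are generated lazily by [expand_formation()].
#'
#' @name allelic_graph
NULL

#' Add one allele to one locus
#'
#' @param formation An `allelic_formation`.
#' @param locus Locus label.
#' @param allele Allele label to append at `locus`; must not already be
#'   present (a repeated allele is a non-novel event, signalled as an error
#'   of class `nashevol_non_novel` so callers can classify it).
#' @return A new `allelic_formation`; the input is unmodified.
#' @export
expand_formation <- function(formation, locus, allele) {
  stop_if_not_formation(formation)
  i <- match(locus, formation$loci)
  if (is.na(i)) stop(sprintf("unknown locus '%s'", locus))
  if (allele %in% formation$alleles[[i]])
    stop(structure(class = c("nashevol_non_novel", "error", "condition"),
                   list(message = sprintf(
                     "allele '%s' is already present at locus '%s' (non-novel event)",
                     allele, locus), call = sys.call(-1L))))
  al <- formation$alleles
  al[[i]] <- c(al[[i]], allele)
  allelic_formation(al)
}

#' Is one formation a single-allele expansion of another?
#'
#' @param f1,f2 `allelic_formation` objects over the same loci.
#' @return A list with `is_edge` (logical), and when `TRUE` also `locus` and
#'   `allele` identifying the added allele.
#' @export
is_expansion_edge <- function(f1, f2) {
  stop_if_not_formation(f1); stop_if_not_formation(f2)
  if (!identical(f1$loci, f2$loci)) return(list(is_edge = FALSE))
  added <- NULL
  for (l in f1$loci) {
    a1 <- f1$alleles[[l]]; a2 <- f2$alleles[[l]]
    if (identical(a1, a2)) next
    # must be a1 with exactly one allele appended
    if (length(a2) != length(a1) + 1L || !identical(a2[seq_along(a1)], a1))
      return(list(is_edge = FALSE))
    if (!is.null(added)) return(list(is_edge = FALSE))  # two loci changed
    added <- list(locus = l, allele = a2[length(a2)])
  }
  if (is.null(added)) return(list(is_edge = FALSE))     # identical formations
  c(list(is_edge = TRUE), added)
}

#' Dimension of a formation
#'
#' The dimension of the genotype simplex of the formation,
#' \eqn{\prod_i |A_i| - 1}. It strictly increases along every expansion
#' edge, so walks up the formation graph move into ever larger state spaces.
#'
#' @param formation An `allelic_formation`.
#' @return Non-negative integer.
#' @export
formation_dimension <- function(formation) {
  stop_if_not_formation(formation)
  prod(lengths(formation$alleles)) - 1
}

#' Restrict a game to a sub-formation
#'
#' Extracts the common-interests game played when only a subset of each
#' locus's alleles is available, keeping the fitness of the surviving
#' genotypes. Used to carve the current game out of a master landscape (an
#' allele universe represented as a `ci_game` over the full pools).
#'
#' @param game A `ci_game` (the larger game).
#' @param formation An `allelic_formation` whose allele sets are subsets of
#'   the game's, same loci.
#' @return A `ci_game` over `formation`.
#' @export
subgame <- function(game, formation) {
  stop_if_not_game(game)
  stop_if_not_formation(formation)
  if (!identical(game$formation$loci, formation$loci))
    stop("formation loci do not match the game")
  for (l in formation$loci) {
    bad <- setdiff(formation$alleles[[l]], game$formation$alleles[[l]])
    if (length(bad))
      stop(sprintf("allele(s) %s at locus '%s' are not in the game",
                   paste(bad, collapse = ", "), l))
  }
  gm <- enumerate_genotypes(formation)
  common_interests_game(formation, game$fitness[rownames(gm)])
}

#' Expand a game by one allele drawn from a universe
#'
#' Follows one edge of the graph of games: appends `allele` to `locus` and
#' pulls the fitness of the newly feasible genotypes from `universe`, a
#' `ci_game` over the full allele pools.
#'
#' @param game Current `ci_game` (must be a subgame of `universe`).
#' @param locus,allele The added allele.
#' @param universe Master `ci_game` supplying fitness for all potential
#'   genotypes.
#' @return The expanded `ci_game`.
#' @export
expand_game <- function(game, locus, allele, universe) {
  stop_if_not_game(game); stop_if_not_game(universe)
  f2 <- expand_formation(game$formation, locus, allele)
  subgame(universe, f2)
}

#' Are all allele pools exhausted?
#'
#' @param formation Current `allelic_formation`.
#' @param universe Master `ci_game` (or `allelic_formation`) holding the
#'   per-locus pools.
#' @return `TRUE` when every pool allele is already present, so no further
#'   novel mutation is possible.
#' @export
universe_exhausted <- function(formation, universe) {
  pools <- if (is_ci_game(universe)) universe$formation$alleles
           else universe$alleles
  all(vapply(formation$loci, function(l)
    length(setdiff(pools[[l]], formation$alleles[[l]])) == 0L, logical(1L)))
}
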