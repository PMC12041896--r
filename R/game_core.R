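#' Allelic formations
#'
#' An allelic formation is the profile of allele sets currently available in
#' the population, one ordered set per locus. Regarding the loci as players
#' and the alleles as their actions, a formation is the action-set profile of
#' the common-interests game the loci play.
#'
#' @param alleles Named list of character vectors; names are locus labels,
#'   entries the (ordered) alleles available at that locus. Every locus must
#'   carry at least one allele and allele labels must be unique within a
#'   locus.
#' @return An object of class `allelic_formation` with fields `loci`
#'   (character vector of locus labels) and `alleles` (named list of allele
#'   vectors).
#' @examples
#' f <- allelic_formation(list(A = c("a1", "a2"), B = c("b1", "b2")))
#' formation_dimension(f)
#' @export
allelic_formation <- function(alleles) {
  if (!is.list(alleles) || length(alleles) < 1L)
    stop("`alleles` must be a non-empty named list of allele vectors")
  loci <- names(alleles)
  if (is.null(loci) || any(is.na(loci)) || any(!nzchar(loci)))
    stop("every locus must have a non-empty name")
  if (anyDuplicated(loci))
    stop("locus labels must be unique")
  alleles <- lapply(alleles, as.character)
  for (i in seq_along(alleles)) {
    a <- alleles[[i]]
    if (length(a) < 1L)
      stop(sprintf("locus '%s' has no alleles", loci[i]))
    if (anyDuplicated(a))
      stop(sprintf("allele labels at locus '%s' are not unique", loci[i]))
    if (any(is.na(a)) || any(!nzchar(a)))
      stop(sprintf("allele labels at locus '%s' must be non-empty strings", loci[i]))
    if (any(grepl(",", a, fixed = TRUE)))
      stop(sprintf("allele labels at locus '%s' must not contain ','", loci[i]))
  }
  structure(list(loci = loci, alleles = alleles), class = "allelic_formation")
}

#' @export
print.allelic_formation <- function(x, ...) {
  cat("Allelic formation:", length(x$loci), "loci\n")
  for (l in x$loci)
    cat(sprintf("  %s: {%s}\n", l, paste(x$alleles[[l]], collapse = ", ")))
  invisible(x)
}

is_formation <- function(x) inherits(x, "allelic_formation")

stop_if_not_formation <- function(x) {
  if (!is_formation(x)) stop("expected an `allelic_formation`")
  invisible(x)
}

#' Enumerate the genotypes of a formation
#'
#' Genotypes are strings of alleles, one per locus; the genotype space is the
#' Cartesian product of the per-locus allele sets. The order is
#' lexicographic: the first locus varies slowest, the last locus fastest,
#' each within its allele-list order. All state vectors in the package are
#' indexed by this order, which is stable across calls.
#'
#' @param formation An `allelic_formation`.
#' @return Character matrix with one row per genotype and one column per
#'   locus; row names are the comma-joined genotype keys.
#' @export
enumerate_genotypes <- function(formation) {
  stop_if_not_formation(formation)
  al <- formation$alleles
  m <- length(al)
  # expand.grid varies its first factor fastest; feed loci reversed so the
  # last locus is fastest, then restore column order
  g <- expand.grid(rev(al), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(g[, rev(seq_len(m)), drop = FALSE])
  colnames(g) <- formation$loci
  rownames(g) <- apply(g, 1L, paste, collapse = ",")
  g
}

#' Genotype keys
#'
#' @param g Character vector (one genotype) or matrix (one genotype per row).
#' @return Comma-joined key string(s), in locus order.
#' @export
genotype_key <- function(g) {
  if (is.matrix(g)) apply(g, 1L, paste, collapse = ",")
  else paste(g, collapse = ",")
}

#' Common-interests game of a formation
#'
#' Binds a formation to a strictly positive fitness value for every genotype
#' in its product space. All loci receive the genotype's fitness as their
#' common payoff, so population mean fitness is a potential function for the
#' game.
#'
#' @param formation An `allelic_formation`.
#' @param fitness Numeric vector of strictly positive fitness values, either
#'   named by genotype key (any order, must cover the genotype space exactly)
#'   or unnamed in the order of [enumerate_genotypes()].
#' @param generic If `TRUE`, assert that the fitness-maximal genotype is
#'   unique.
#' @return An object of class `ci_game` with fields `formation`, `genotypes`
#'   (the enumeration matrix), `fitness` (named, in enumeration order), and
#'   index helpers used by the dynamics.
#' @examples
#' g <- example_matrix(1, delta = 0.25)
#' pure_nash(g)
#' @export
common_interests_game <- function(formation, fitness, generic = FALSE) {
  stop_if_not_formation(formation)
  gm <- enumerate_genotypes(formation)
  keys <- rownames(gm)
  if (!is.numeric(fitness)) stop("`fitness` must be numeric")
  if (!is.null(names(fitness))) {
    missing <- setdiff(keys, names(fitness))
    if (length(missing))
      stop(sprintf("fitness missing for genotype(s): %s",
                   paste(missing, collapse = "; ")))
    extra <- setdiff(names(fitness), keys)
    if (length(extra))
      stop(sprintf("fitness given for unknown genotype(s): %s",
                   paste(extra, collapse = "; ")))
    if (anyDuplicated(names(fitness)))
      stop("duplicate genotype keys in `fitness`")
    w <- unname(fitness[keys])
  } else {
    if (length(fitness) != nrow(gm))
      stop(sprintf("fitness has length %d but the formation has %d genotypes",
                   length(fitness), nrow(gm)))
    w <- unname(fitness)
  }
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all fitness values must be finite and strictly positive")
  if (generic && sum(w == max(w)) > 1L)
    stop("game is not generic: fitness-maximal genotype is not unique")
  names(w) <- keys
  # integer allele index per locus (1-based), used by the compiled dynamics
  gidx <- vapply(seq_along(formation$loci), function(i)
    match(gm[, i], formation$alleles[[i]]), integer(nrow(gm)))
  gidx <- matrix(gidx, nrow = nrow(gm))
  structure(list(formation = formation, genotypes = gm, fitness = w,
                 gidx = gidx,
                 n_alleles = lengths(formation$alleles)),
            class = "ci_game")
}

#' @export
print.ci_game <- function(x, ...) {
  cat(sprintf("Common-interests game: %d loci, %d genotypes\n",
              length(x$formation$loci), nrow(x$genotypes)))
  print(x$formation)
  cat(sprintf("  fitness in [%g, %g], maximum at %s\n",
              min(x$fitness), max(x$fitness),
              names(x$fitness)[which.max(x$fitness)]))
  invisible(x)
}

is_ci_game <- function(x) inherits(x, "ci_game")

stop_if_not_game <- function(x) {
  if (!is_ci_game(x)) stop("expected a `ci_game`")
  invisible(x)
}

#' Genotypic population state
#'
#' A probability vector over the genotypes of a game: the state of an asexual
#' population. A state is monomorphic when it places unit mass on one
#' genotype.
#'
#' @param game A `ci_game`.
#' @param weights Numeric vector of non-negative weights, named by genotype
#'   key or ordered as [enumerate_genotypes()]. Must sum to 1 within 1e-12.
#' @return Named numeric vector in enumeration order.
#' @export
genotype_state <- function(game, weights) {
  stop_if_not_game(game)
  keys <- names(game$fitness)
  if (!is.null(names(weights))) {
    missing <- setdiff(keys, names(weights))
    if (length(missing))
      stop(sprintf("weights missing for genotype(s): %s",
                   paste(missing, collapse = "; ")))
    w <- unname(weights[keys])
  } else {
    if (length(weights) != length(keys))
      stop("genotypic state has wrong length")
    w <- unname(weights)
  }
  if (any(!is.finite(w)) || any(w < 0))
    stop("genotypic weights must be finite and non-negative")
  if (abs(sum(w) - 1) > 1e-12)
    stop("genotypic weights must sum to 1 (within 1e-12)")
  names(w) <- keys
  w
}

#' Allelic population state
#'
#' One probability vector per locus over that locus's alleles: the state of a
#' sexual population under full recombination (no correlation across loci).
#' The state space is the multi-simplex, the product of the per-locus
#' simplices.
#'
#' @param formation An `allelic_formation` (or a `ci_game`, whose formation
#'   is used).
#' @param per_locus Named list (by locus) of non-negative numeric vectors,
#'   each summing to 1 within 1e-12; entries may be named by allele or
#'   ordered as the locus's allele list.
#' @return Named list of named per-locus frequency vectors, in locus order.
#' @export
allelic_state <- function(formation, per_locus) {
  if (is_ci_game(formation)) formation <- formation$formation
  stop_if_not_formation(formation)
  if (!is.list(per_locus)) stop("`per_locus` must be a list")
  if (is.null(names(per_locus))) {
    if (length(per_locus) != length(formation$loci))
      stop("allelic state has wrong number of loci")
    names(per_locus) <- formation$loci
  }
  missing <- setdiff(formation$loci, names(per_locus))
  if (length(missing))
    stop(sprintf("allelic state missing locus/loci: %s",
                 paste(missing, collapse = ", ")))
  out <- vector("list", length(formation$loci))
  names(out) <- formation$loci
  for (l in formation$loci) {
    a <- formation$alleles[[l]]
    v <- per_locus[[l]]
    if (!is.null(names(v))) {
      if (!setequal(names(v), a))
        stop(sprintf("allelic state at locus '%s' does not match its alleles", l))
      v <- unname(v[a])
    }
    if (length(v) != length(a))
      stop(sprintf("allelic state at locus '%s' has wrong length", l))
    if (any(!is.finite(v)) || any(v < 0))
      stop(sprintf("frequencies at locus '%s' must be finite and non-negative", l))
    if (abs(sum(v) - 1) > 1e-12)
      stop(sprintf("frequencies at locus '%s' must sum to 1 (within 1e-12)", l))
    names(v) <- a
    out[[l]] <- v
  }
  out
}

# flatten/unflatten between the named-list and concatenated representations
flatten_allelic <- function(q) unlist(q, use.names = FALSE)

unflatten_allelic <- function(formation, x) {
  n <- lengths(formation$alleles)
  ends <- cumsum(n)
  starts <- ends - n + 1L
  out <- lapply(seq_along(n), function(i) {
    v <- x[starts[i]:ends[i]]
    names(v) <- formation$alleles[[i]]
    v
  })
  names(out) <- formation$loci
  out
}

allelic_colnames <- function(formation) {
  unlist(lapply(formation$loci, function(l)
    paste(l, formation$alleles[[l]], sep = ":")), use.names = FALSE)
}

#' Mean fitness of a genotypic state
#'
#' \eqn{w(p) = \sum_g w_g p_g}, the potential ascended by the asexual
#' replicator dynamics.
#'
#' @param game A `ci_game`.
#' @param p Genotypic state (see [genotype_state()]).
#' @return Positive scalar.
#' @export
mean_fitness_genotypic <- function(game, p) {
  stop_if_not_game(game)
  if (length(p) != length(game$fitness))
    stop("genotypic state length does not match the game")
  sum(game$fitness * as.numeric(p))
}

# multilinear mean fitness, no simplex validation (used by finite differences)
mean_fitness_allelic_raw <- function(game, qflat) {
  n <- game$n_alleles
  off <- c(0L, cumsum(n))[seq_along(n)]
  prods <- rep(1, nrow(game$gidx))
  for (i in seq_along(n))
    prods <- prods * qflat[off[i] + game$gidx[, i]]
  sum(game$fitness * prods)
}

#' Mean fitness of an allelic state
#'
#' \eqn{w(q) = \sum_g w_g \prod_i q^i_{g_i}}: the expectation of genotype
#' fitness under the product distribution induced by the per-locus allele
#' frequencies. Multilinear in the per-locus vectors and the potential
#' ascended by the sexual multi-replicator dynamics.
#'
#' @param game A `ci_game`.
#' @param q Allelic state (see [allelic_state()]).
#' @return Positive scalar.
#' @export
mean_fitness_allelic <- function(game, q) {
  stop_if_not_game(game)
  q <- allelic_state(game$formation, q)
  mean_fitness_allelic_raw(game, flatten_allelic(q))
}

#' Marginal fitness of an allele
#'
#' The payoff to locus `locus` for playing allele `allele` when the rest of
#' the population is described by `q`:
#' \eqn{w_{-i}(q \mid a) = \sum_{g : g_i = a} w_g \prod_{j \ne i} q^j_{g_j}}.
#' It equals the partial derivative of the mean fitness with respect to that
#' allele's frequency, and frequencies-weighted marginals average back to the
#' mean fitness.
#'
#' @param game A `ci_game`.
#' @param q Allelic state.
#' @param locus,allele Labels identifying the allele.
#' @return Positive scalar.
#' @export
marginal_fitness <- function(game, q, locus, allele) {
  stop_if_not_game(game)
  q <- allelic_state(game$formation, q)
  i <- match(locus, game$formation$loci)
  if (is.na(i)) stop(sprintf("unknown locus '%s'", locus))
  j <- match(allele, game$formation$alleles[[i]])
  if (is.na(j)) stop(sprintf("unknown allele '%s' at locus '%s'", allele, locus))
  unname(marginal_fitness_all(game, q)[[i]][j])
}

# marginal fitness of every allele at every locus; list parallel to q
marginal_fitness_all <- function(game, q) {
  qflat <- flatten_allelic(q)
  n <- game$n_alleles
  off <- c(0L, cumsum(n))[seq_along(n)]
  m <- length(n)
  ng <- nrow(game$gidx)
  qs <- matrix(0, ng, m)
  for (i in seq_len(m)) qs[, i] <- qflat[off[i] + game$gidx[, i]]
  out <- vector("list", m)
  for (i in seq_len(m)) {
    # product over the other loci, computed without division (zeros allowed)
    pe <- rep(1, ng)
    for (l in seq_len(m)) if (l != i) pe <- pe * qs[, l]
    contrib <- game$fitness * pe
    v <- as.numeric(rowsum(contrib, group = game$gidx[, i]))
    # rowsum drops absent groups; map back onto the full allele list
    full <- numeric(n[i])
    full[sort(unique(game$gidx[, i]))] <- v
    names(full) <- game$formation$alleles[[i]]
    out[[i]] <- full
  }
  names(out) <- game$formation$loci
  out
}

#' Allelic state induced by a genotypic state
#'
#' The per-locus marginal allele frequencies of a distribution over
#' genotypes: \eqn{q^i_a = \sum_{g : g_i = a} p_g}.
#'
#' @param game A `ci_game`.
#' @param p Genotypic state.
#' @return Allelic state (named list of per-locus frequency vectors).
#' @export
allelic_state_of <- function(game, p) {
  stop_if_not_game(game)
  p <- genotype_state(game, p)
  f <- game$formation
  out <- lapply(seq_along(f$loci), function(i) {
    v <- numeric(game$n_alleles[i])
    grp <- game$gidx[, i]
    for (k in seq_along(p)) v[grp[k]] <- v[grp[k]] + p[k]
    names(v) <- f$alleles[[i]]
    v
  })
  names(out) <- f$loci
  out
}

#' Pure Nash equilibria of a common-interests game
#'
#' A genotype is a pure Nash equilibrium when no single-locus allele
#' substitution raises fitness; it is strict when every substitution strictly
#' lowers it. In a common-interests game these are exactly the local maxima
#' of the fitness landscape under single-allele moves, and the strict ones
#' are the possible monomorphic limits of the sexual dynamics.
#'
#' @param game A `ci_game`.
#' @param strict If `TRUE` (default), return strict equilibria only.
#' @return Character matrix of equilibrium genotypes (possibly zero rows),
#'   one per row in enumeration order, row names the genotype keys.
#' @export
pure_nash <- function(game, strict = TRUE) {
  stop_if_not_game(game)
  w <- game$fitness
  n <- game$n_alleles
  m <- length(n)
  ng <- length(w)
  # row strides of the lexicographic enumeration: last locus fastest
  stride <- integer(m)
  s <- 1L
  for (i in m:1) { stride[i] <- s; s <- s * n[i] }
  keep <- rep(TRUE, ng)
  for (r in seq_len(ng)) {
    for (i in seq_len(m)) {
      ji <- game$gidx[r, i]
      sib <- r + (seq_len(n[i]) - ji) * stride[i]
      others <- sib[sib != r]
      if (length(others)) {
        if (strict) {
          if (any(w[others] >= w[r])) { keep[r] <- FALSE; break }
        } else {
          if (any(w[others] > w[r])) { keep[r] <- FALSE; break }
        }
      }
    }
  }
  game$genotypes[keep, , drop = FALSE]
}
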