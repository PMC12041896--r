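# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms/data paths than the package.

# exhaustive deviation scan over the genotype table: g is Nash iff no row
# differing at exactly one locus has (weakly/strictly) higher fitness
oracle_nash <- function(game, strict = TRUE) {
  gm <- game$genotypes
  w <- game$fitness
  m <- ncol(gm)
  keep <- logical(nrow(gm))
  for (r in seq_len(nrow(gm))) {
    ok <- TRUE
    for (s in seq_len(nrow(gm))) {
      if (s == r) next
      ndiff <- sum(gm[r, ] != gm[s, ])
      if (ndiff == 1L) {
        if (strict && w[s] >= w[r]) { ok <- FALSE; break }
        if (!strict && w[s] > w[r]) { ok <- FALSE; break }
      }
    }
    keep[r] <- ok
  }
  rownames(gm)[keep]
}

# exhaustive valley scan: all ordered pairs of local maxima, with the
# geodesic-intermediate condition checked against every local maximum
oracle_valleys <- function(game) {
  lm <- oracle_nash(game, strict = TRUE)
  gm <- game$genotypes
  w <- game$fitness
  dh <- function(x, y) sum(gm[x, ] != gm[y, ])
  out <- character(0)
  for (g1 in lm) for (g2 in lm) {
    if (g1 == g2) next
    if (!(w[g2] > w[g1])) next
    if (dh(g1, g2) < 2L) next
    on_path <- vapply(setdiff(lm, c(g1, g2)), function(g3)
      dh(g1, g3) + dh(g3, g2) == dh(g1, g2), logical(1L))
    if (!any(on_path)) out <- c(out, paste(g1, g2, sep = "->"))
  }
  sort(out)
}

# reference integration of the replicator fields with deSolve (R-side
# field evaluation, independent of the compiled integrator)
ref_integrate <- function(game, state, mode, times) {
  if (mode == "sexual") {
    q0 <- allelic_state(game$formation, state)
    x0 <- unlist(q0, use.names = FALSE)
    rhs <- function(t, x, parms) {
      q <- nashevol:::unflatten_allelic(game$formation, x)
      list(unlist(multireplicator_field(game, q), use.names = FALSE))
    }
  } else {
    x0 <- as.numeric(genotype_state(game, state))
    rhs <- function(t, x, parms) list(as.numeric(replicator_field(game, x / sum(x))))
  }
  deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
               rtol = 1e-10, atol = 1e-12)
}

# closed form of the genotypic replicator: p(t) proportional to p0 * exp(w t)
asex_closed_form <- function(game, p0, t) {
  x <- as.numeric(p0) * exp(game$fitness * t)
  x / sum(x)
}

# uniform interior point of a k-simplex
rdirichlet1 <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}

# the shared worked-example start (Example 1/2): mass 1 - eps on (a1,b1)
example_start <- function(game, eps = 0.01) {
  w <- setNames(numeric(length(game$fitness)), names(game$fitness))
  w["a1,b1"] <- 1 - eps
  w["a2,b1"] <- eps / 2
  w["a1,b2"] <- eps / 2
  genotype_state(game, w)
}
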