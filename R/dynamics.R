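#' Genotypic replicator field
#'
#' The asexual dynamics: each genotype grows at its fitness excess over the
#' population mean, \eqn{\dot p_g = p_g (w_g - w(p))}. Components sum to
#' zero, so the simplex is invariant; vertices are fixed points.
#'
#' @param game A `ci_game`.
#' @param p Genotypic state.
#' @return Named numeric velocity vector over genotypes.
#' @export
replicator_field <- function(game, p) {
  stop_if_not_game(game)
  p <- genotype_state(game, p)
  wbar <- sum(game$fitness * p)
  p * (game$fitness - wbar)
}

#' Allelic multi-replicator field
#'
#' The sexual dynamics under full recombination: within each locus the
#' alleles run a replicator on their marginal fitness,
#' \eqn{\dot q^i_j = q^i_j (w^i_j(q) - w(q))}, coupled across loci through
#' the marginals. Per-locus components sum to zero; pure-strategy vertices
#' are fixed points.
#'
#' @param game A `ci_game`.
#' @param q Allelic state.
#' @return Named list (by locus) of velocity vectors.
#' @export
multireplicator_field <- function(game, q) {
  stop_if_not_game(game)
  q <- allelic_state(game$formation, q)
  wbar <- mean_fitness_allelic_raw(game, flatten_allelic(q))
  marg <- marginal_fitness_all(game, q)
  out <- lapply(seq_along(q), function(i) q[[i]] * (marg[[i]] - wbar))
  names(out) <- game$formation$loci
  out
}

#' Default dynamics configuration
#'
#' Tolerances and horizon for [integrate_to_equilibrium()]. The integrator
#' is an adaptive Runge-Kutta 4(5) pair; `tol_v` stops on the velocity
#' max-norm, `tol_m` on the leading mass of every simplex block, `horizon`
#' caps integration time, and `n_grid` sets the (log-spaced) number of
#' recorded snapshots.
#'
#' @param horizon,tol_v,tol_m,rtol,atol,n_grid Overrides of the defaults.
#' @return Named list of settings.
#' @export
dynamics_config <- function(horizon = 1e4, tol_v = 1e-9, tol_m = 1e-6,
                            rtol = 1e-8, atol = 1e-10, n_grid = 120) {
  stopifnot(horizon >= 0, tol_v > 0, tol_m > 0, rtol > 0, atol > 0,
            n_grid >= 2)
  list(horizon = horizon, tol_v = tol_v, tol_m = tol_m, rtol = rtol,
       atol = atol, n_grid = n_grid)
}

time_grid <- function(horizon, n_grid) {
  if (horizon <= 0) return(0)
  t1 <- min(0.01, horizon / n_grid)
  c(0, exp(seq(log(t1), log(horizon), length.out = n_grid - 1L)))
}

#' Integrate a population flow to equilibrium
#'
#' Runs the genotypic replicator (`mode = "asexual"`) or the allelic
#' multi-replicator (`mode = "sexual"`) from an initial state until the
#' velocity max-norm falls below `tol_v`, every simplex block concentrates
#' mass above `1 - tol_m`, or the horizon is reached. Mean fitness is
#' non-decreasing along the flow (both dynamics are gradient ascent of mean
#' fitness in the Shahshahani geometry), and from interior starts the sexual
#' flow converges to a monomorphic strict pure Nash equilibrium while the
#' asexual flow converges to the fittest genotype present.
#'
#' @param game A `ci_game`.
#' @param state Initial [genotype_state()] (asexual) or [allelic_state()]
#'   (sexual). Coordinates exactly 0 stay 0 (the flow preserves faces);
#'   interior starts are required for the Nash convergence guarantee and
#'   non-interior starts are flagged in the result.
#' @param mode `"sexual"` or `"asexual"`.
#' @param config See [dynamics_config()]; `horizon` may also be passed
#'   directly.
#' @param horizon Optional override of `config$horizon`.
#' @return An `evo_trajectory`: list with `times`, `states` (matrix, one row
#'   per snapshot; columns `locus:allele` or genotype keys), `mean_fitness`,
#'   `converged`, `reason`, `limit` (genotype key of the attributed
#'   equilibrium when converged: nearest strict pure Nash for sexual mode,
#'   modal genotype for asexual), `limit_fitness`, `mode`, `interior`,
#'   `final_state`, and the `game`.
#' @export
integrate_to_equilibrium <- function(game, state,
                                     mode = c("sexual", "asexual"),
                                     config = dynamics_config(),
                                     horizon = NULL) {
  stop_if_not_game(game)
  mode <- match.arg(mode)
  if (!is.null(horizon)) config$horizon <- horizon
  sexual <- mode == "sexual"
  if (sexual) {
    q <- allelic_state(game$formation, state)
    x0 <- flatten_allelic(q)
    cn <- allelic_colnames(game$formation)
  } else {
    x0 <- as.numeric(genotype_state(game, state))
    cn <- names(game$fitness)
  }
  interior <- all(x0 > 0)
  grid <- time_grid(config$horizon, config$n_grid)
  strict_keys <- rownames(pure_nash(game, strict = TRUE))
  is_nash <- as.integer(names(game$fitness) %in% strict_keys)
  res <- cpp_integrate(unname(game$fitness), game$gidx,
                       as.integer(game$n_alleles), x0, sexual, grid,
                       config$tol_v, config$tol_m, config$rtol, config$atol,
                       is_nash)
  states <- res$states
  colnames(states) <- cn
  final <- states[nrow(states), ]
  limit <- NA_character_
  limit_fitness <- NA_real_
  if (sexual) {
    fq <- unflatten_allelic(game$formation, final)
    nash <- pure_nash(game, strict = TRUE)
    if (nrow(nash) > 0L) {
      d <- vapply(seq_len(nrow(nash)), function(r)
        l1_to_vertex(game, fq, nash[r, ]), numeric(1L))
      limit <- rownames(nash)[which.min(d)]
      limit_fitness <- unname(game$fitness[limit])
    }
    final_state <- fq
  } else {
    limit <- names(game$fitness)[which.max(final)]
    limit_fitness <- unname(game$fitness[limit])
    final_state <- final
  }
  structure(list(times = res$times, states = states,
                 mean_fitness = res$mean_fitness,
                 converged = res$converged, reason = res$reason,
                 velocity_norm = res$velocity_norm,
                 limit = limit, limit_fitness = limit_fitness,
                 mode = mode, interior = interior,
                 final_state = final_state, game = game),
            class = "evo_trajectory")
}

#' @export
print.evo_trajectory <- function(x, ...) {
  cat(sprintf(
    "%s trajectory: %d snapshots over [0, %.4g], %s (%s)\n",
    x$mode, length(x$times), max(x$times),
    if (x$converged) "converged" else "not converged", x$reason))
  cat(sprintf("  mean fitness %.6g -> %.6g; attributed limit %s (w = %g)\n",
              x$mean_fitness[1], x$mean_fitness[length(x$mean_fitness)],
              x$limit, x$limit_fitness))
  invisible(x)
}

# L1 distance from allelic state q to the vertex of genotype g, summed
# over loci
l1_to_vertex <- function(game, q, g) {
  f <- game$formation
  d <- 0
  for (i in seq_along(f$loci)) {
    v <- numeric(game$n_alleles[i])
    v[match(g[i], f$alleles[[i]])] <- 1
    d <- d + sum(abs(q[[i]] - v))
  }
  d
}

#' Distance from a state to the pure Nash set
#'
#' L1 distance (summed over the per-locus simplices) from an allelic state
#' to the nearest vertex of a pure Nash genotype. Zero exactly at a Nash
#' vertex; at most twice the number of loci.
#'
#' @param game A `ci_game`.
#' @param state Allelic state.
#' @param strict Use strict pure Nash equilibria (default) or weak ones.
#' @return Non-negative scalar.
#' @export
distance_to_nash <- function(game, state, strict = TRUE) {
  stop_if_not_game(game)
  q <- allelic_state(game$formation, state)
  nash <- pure_nash(game, strict = strict)
  if (nrow(nash) == 0L)
    stop("the game has no pure Nash equilibria of the requested kind")
  min(vapply(seq_len(nrow(nash)), function(r)
    l1_to_vertex(game, q, nash[r, ]), numeric(1L)))
}

#' Shahshahani gradient residual of the multi-replicator field
#'
#' Numerically certifies that the sexual dynamics is gradient ascent of mean
#' fitness under the Shahshahani metric (coordinate \eqn{(i,j)} weighted by
#' \eqn{1/q^i_j}). The gradient is assembled from central finite differences
#' of [mean_fitness_allelic()] projected onto each simplex tangent space and
#' compared with [multireplicator_field()] in max-norm.
#'
#' @param game A `ci_game`.
#' @param q Strictly interior allelic state.
#' @param h Finite-difference step (default `1e-5`).
#' @return Non-negative residual; small values certify the gradient
#'   structure at `q`.
#' @export
shahshahani_residual <- function(game, q, h = 1e-5) {
  stop_if_not_game(game)
  q <- allelic_state(game$formation, q)
  if (any(vapply(q, function(v) any(v <= 0), logical(1L))))
    stop("the Shahshahani metric degenerates on the boundary; `q` must be interior")
  qflat <- flatten_allelic(q)
  n <- game$n_alleles
  off <- c(0L, cumsum(n))[seq_along(n)]
  fld <- multireplicator_field(game, q)
  resid <- 0
  for (i in seq_along(n)) {
    # unconstrained central differences of the multilinear extension
    d <- numeric(n[i])
    for (j in seq_len(n[i])) {
      e <- numeric(length(qflat)); e[off[i] + j] <- h
      d[j] <- (mean_fitness_allelic_raw(game, qflat + e) -
               mean_fitness_allelic_raw(game, qflat - e)) / (2 * h)
    }
    # Shahshahani gradient on the simplex: q_j (d_j - sum_k q_k d_k)
    grad <- q[[i]] * (d - sum(q[[i]] * d))
    resid <- max(resid, max(abs(fld[[i]] - grad)))
  }
  resid
}
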