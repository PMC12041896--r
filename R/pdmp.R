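#' Sample the next mutation event
#'
#' A Poisson clock with rate `lambda` fires after an Exponential(`lambda`)
#' waiting time; a locus is then chosen uniformly and an allele uniformly
#' from that locus's universe pool. The sampled allele may already be
#' present in the current formation, in which case the event is non-novel.
#' Uses the current RNG state.
#'
#' @param formation Current `allelic_formation`.
#' @param universe Master `ci_game` (or formation) holding the per-locus
#'   pools; the current formation must be contained in it.
#' @param lambda Positive clock rate.
#' @return List with `wait`, `locus`, `allele`, `novel` (logical).
#' @export
sample_next_event <- function(formation, universe, lambda) {
  stop_if_not_formation(formation)
  if (!is.numeric(lambda) || lambda <= 0) stop("`lambda` must be positive")
  pools <- if (is_ci_game(universe)) universe$formation$alleles
           else universe$alleles
  wait <- stats::rexp(1L, rate = lambda)
  locus <- formation$loci[sample.int(length(formation$loci), 1L)]
  pool <- pools[[locus]]
  allele <- pool[sample.int(length(pool), 1L)]
  list(wait = wait, locus = locus, allele = allele,
       novel = !(allele %in% formation$alleles[[locus]]))
}

#' Embed an allelic state into an expanded formation
#'
#' After a novel mutation the state lives in a higher-dimensional
#' multi-simplex. At the mutated locus the new allele receives frequency
#' `eps_mut` and the existing frequencies are scaled by `1 - eps_mut`; the
#' other loci are untouched. A strictly positive injection is required
#' because the replicator dynamics cannot grow an allele from frequency
#' zero.
#'
#' @param q Allelic state on the pre-mutation formation.
#' @param formation The pre-mutation `allelic_formation`.
#' @param locus,allele The added allele.
#' @param eps_mut Injection frequency, in (0, 1). Default `1e-3`.
#' @return Allelic state on the expanded formation.
#' @export
embed_state <- function(q, formation, locus, allele, eps_mut = 1e-3) {
  stop_if_not_formation(formation)
  if (!is.numeric(eps_mut) || eps_mut <= 0 || eps_mut >= 1)
    stop("`eps_mut` must lie strictly between 0 and 1")
  q <- allelic_state(formation, q)
  f2 <- expand_formation(formation, locus, allele)
  v <- c(q[[locus]] * (1 - eps_mut), eps_mut)
  names(v) <- f2$alleles[[locus]]
  q[[locus]] <- v
  allelic_state(f2, q)
}

#' Inject a genotype into a genotypic state
#'
#' Moves mass `eps` onto one genotype (rescaling the rest), e.g. to model a
#' mutant individual appearing in an asexual population.
#'
#' @param game A `ci_game`.
#' @param p Genotypic state.
#' @param genotype Character vector of alleles (or a genotype key).
#' @param eps Mass to place on the genotype, in (0, 1).
#' @return Genotypic state.
#' @export
inject_genotype <- function(game, p, genotype, eps) {
  stop_if_not_game(game)
  p <- genotype_state(game, p)
  if (eps <= 0 || eps >= 1) stop("`eps` must lie strictly between 0 and 1")
  key <- if (length(genotype) > 1L) genotype_key(genotype) else genotype
  if (!key %in% names(p)) stop(sprintf("unknown genotype '%s'", key))
  p <- p * (1 - eps)
  p[key] <- p[key] + eps
  genotype_state(game, p)
}

#' Classify a mutation event
#'
#' A mutation that adds no new allele is `non_novel`: the same game
#' continues and the population stays put. A novel mutation is
#' `game_changing`: the loci now play a larger game. It is in addition
#' `nash_changing` when the previously occupied equilibrium `g1` is not a
#' pure Nash equilibrium of the expanded game, so the population must move
#' to a new, fitter equilibrium.
#'
#' @param old_game `ci_game` before the event.
#' @param g1 Occupied equilibrium of `old_game` (allele vector or key);
#'   must be a pure Nash equilibrium of `old_game`.
#' @param new_game `ci_game` after the event (equal to `old_game` for a
#'   non-novel event).
#' @param strict Use strict pure Nash membership (default, matching the
#'   monomorphic limits of the dynamics).
#' @return One of `"non_novel"`, `"game_changing"`, `"nash_changing"`.
#' @export
classify_event <- function(old_game, g1, new_game, strict = TRUE) {
  stop_if_not_game(old_game); stop_if_not_game(new_game)
  key <- if (length(g1) > 1L) genotype_key(g1) else g1
  if (!key %in% rownames(pure_nash(old_game, strict = strict)))
    stop(sprintf("'%s' is not a pure Nash equilibrium of the pre-event game", key))
  if (identical(old_game$formation, new_game$formation)) return("non_novel")
  edge <- is_expansion_edge(old_game$formation, new_game$formation)
  if (!isTRUE(edge$is_edge))
    stop("the two games are not connected by a single expansion edge")
  if (key %in% rownames(pure_nash(new_game, strict = strict)))
    "game_changing" else "nash_changing"
}

# Integrate one inter-event segment and attribute its end equilibrium.
# With horizon = NULL the segment relaxes to equilibrium (the rare-mutation
# reading); otherwise it runs for exactly the waiting time and, when that
# leaves the flow mid-transit, the occupied equilibrium is attributed by
# the basin limit: a continuation integration from the segment-end state.
segment_run <- function(game, q, config, wait = NULL) {
  traj <- integrate_to_equilibrium(game, q, mode = "sexual", config = config,
                                   horizon = wait)
  eq <- traj$limit
  eq_fitness <- traj$limit_fitness
  if (!is.null(wait) && !traj$converged) {
    cont <- integrate_to_equilibrium(game, traj$final_state, mode = "sexual",
                                     config = config)
    eq <- cont$limit
    eq_fitness <- cont$limit_fitness
  }
  list(game = game, trajectory = traj, end_state = traj$final_state,
       eq = eq, eq_fitness = eq_fitness)
}

#' Simulate the mutation-driven piecewise-deterministic process
#'
#' Alternates deterministic multi-replicator flow with Poisson-arriving
#' mutation events drawn from an allele universe. After a novel event the
#' segment-end state is embedded into the expanded multi-simplex with the
#' new allele at frequency `eps_mut` and the flow continues under the
#' expanded game. Events are classified against the equilibrium occupied at
#' the segment end. Non-novel events are recorded but leave the state
#' untouched. After the last event a closing segment is integrated to
#' convergence so every event has a post-event equilibrium.
#'
#' Two readings of the inter-event flow are available. With
#' `relax = "converge"` (default) each segment relaxes to its equilibrium
#' before the next event applies — the rare-mutation (jump-chain) reading
#' under which the sequence of segment-end equilibrium fitness values is
#' weakly increasing and rises strictly exactly at Nash-changing events.
#' With `relax = "wait"` each segment runs for exactly its sampled waiting
#' time (the finite-rate process); segments caught mid-transit attribute
#' their occupied equilibrium by the basin limit, a continuation
#' integration from the segment-end state, and when events arrive faster
#' than the flow relaxes the jump-chain invariants need not hold.
#'
#' Uses the current RNG state: `set.seed()` first for a reproducible run.
#'
#' @param universe Master `ci_game` over the full allele pools.
#' @param formation Starting `allelic_formation` (contained in the
#'   universe).
#' @param state Starting allelic state on `formation`; interior recommended.
#' @param lambda Poisson clock rate.
#' @param n_events Maximum number of clock events to simulate.
#' @param eps_mut Injection frequency for novel alleles.
#' @param config Dynamics configuration ([dynamics_config()]); its
#'   `horizon` caps relaxation segments.
#' @param relax `"converge"` (rare-mutation jump chain, default) or
#'   `"wait"` (segments run for exactly the sampled waiting times).
#' @param stop_when_exhausted End the run cleanly once every pool allele is
#'   present (default `TRUE`).
#' @return A `pdmp_run`: list with `segments` (per event: `game`,
#'   `trajectory`, `end_state`, `eq`, `eq_fitness`, `event`), `events`
#'   (data frame with `t`, `locus`, `allele`, `class`, `pre_eq`, `post_eq`,
#'   `pre_w`, `post_w`), `final` (closing segment), `final_state`,
#'   `final_game`, `universe`, `lambda`, `eps_mut`, `relax`, `config`.
#' @export
run_pdmp <- function(universe, formation, state, lambda = 1, n_events = 10,
                     eps_mut = 1e-3, config = dynamics_config(),
                     relax = c("converge", "wait"),
                     stop_when_exhausted = TRUE) {
  stop_if_not_game(universe)
  relax <- match.arg(relax)
  game <- subgame(universe, formation)
  q <- allelic_state(formation, state)
  segments <- list()
  ev_rows <- list()
  t_now <- 0
  for (k in seq_len(n_events)) {
    ev <- sample_next_event(game$formation, universe, lambda)
    seg <- segment_run(game, q, config,
                       wait = if (relax == "wait") ev$wait else NULL)
    t_now <- t_now + ev$wait
    if (ev$novel) {
      new_game <- expand_game(game, ev$locus, ev$allele, universe)
      cls <- classify_event(game, seg$eq, new_game)
      q <- embed_state(seg$end_state, game$formation, ev$locus, ev$allele,
                       eps_mut)
      game <- new_game
    } else {
      cls <- "non_novel"
      q <- seg$end_state
    }
    seg$event <- list(t = t_now, locus = ev$locus, allele = ev$allele,
                      class = cls, wait = ev$wait)
    segments[[k]] <- seg
    ev_rows[[k]] <- data.frame(t = t_now, locus = ev$locus,
                               allele = ev$allele, class = cls,
                               pre_eq = seg$eq, pre_w = seg$eq_fitness,
                               stringsAsFactors = FALSE)
    if (stop_when_exhausted && universe_exhausted(game$formation, universe))
      break
  }
  closing <- segment_run(game, q, config)
  events <- do.call(rbind, ev_rows)
  post_eq <- c(events$pre_eq[-1L], closing$eq)
  post_w <- c(events$pre_w[-1L], closing$eq_fitness)
  events$post_eq <- post_eq
  events$post_w <- post_w
  structure(list(segments = segments, events = events, final = closing,
                 final_state = closing$end_state, final_game = game,
                 universe = universe, lambda = lambda, eps_mut = eps_mut,
                 relax = relax, config = config),
            class = "pdmp_run")
}

#' @export
print.pdmp_run <- function(x, ...) {
  cat(sprintf("PDMP run: %d events (lambda = %g), final equilibrium %s (w = %g)\n",
              nrow(x$events), x$lambda, x$final$eq, x$final$eq_fitness))
  print(table(x$events$class))
  invisible(x)
}

#' Equilibrium fitness snapshots of a run
#'
#' The fitness of the equilibrium occupied at the end of each inter-event
#' segment, followed by the final equilibrium: a weakly increasing sequence
#' that rises strictly exactly at Nash-changing events.
#'
#' @param run A `pdmp_run`.
#' @return Numeric vector of length `n_events + 1`.
#' @export
equilibrium_snapshots <- function(run) {
  c(run$events$pre_w, run$final$eq_fitness)
}

#' Distances to the Nash set near the end of each inter-arrival interval
#'
#' For each segment of a run, evaluates the L1 distance from the trajectory
#' to the pure Nash set of the game in force at sampling fractions of the
#' inter-arrival interval (by default, inside the last 5%). When the
#' segment's flow converged before the interval elapsed, the recorded
#' stationary endpoint stands in for the (unchanged, to tolerance) later
#' state. Used to check that with rare mutations the population is near a
#' Nash equilibrium just before each arrival.
#'
#' @param run A `pdmp_run`.
#' @param fractions Sampling points as fractions of each interval.
#' @return Data frame with `segment`, `fraction`, `distance`.
#' @export
nash_distance_series <- function(run, fractions = c(0.96, 0.98, 1.0)) {
  if (!identical(run$relax, "wait"))
    stop("interval sampling needs a run with relax = \"wait\" (real waiting times)")
  rows <- lapply(seq_along(run$segments), function(k) {
    seg <- run$segments[[k]]
    traj <- seg$trajectory
    g <- seg$game
    ts <- fractions * seg$event$wait
    d <- vapply(ts, function(tt) {
      i <- max(which(traj$times <= tt + 1e-12))
      q <- unflatten_allelic(g$formation, traj$states[i, ])
      distance_to_nash(g, q)
    }, numeric(1L))
    data.frame(segment = k, fraction = fractions, distance = d)
  })
  do.call(rbind, rows)
}

#' Play a scripted mutation path
#'
#' The deterministic converge-embed-converge chain: from the initial state,
#' integrate the current game to equilibrium, apply the next scripted
#' mutation (embedding the new allele at `eps_mut`), and repeat; a final
#' integration closes the path. This is the small-rate limit of
#' [run_pdmp()] with the event order forced.
#'
#' @param universe Master `ci_game`.
#' @param formation Starting formation.
#' @param state Starting allelic state.
#' @param script List of `list(locus =, allele =)` events, applied in
#'   order.
#' @param eps_mut Injection frequency.
#' @param config Dynamics configuration.
#' @return List with `steps` (per scripted event: `game`, `trajectory`,
#'   `class`, `eq`, `eq_fitness`), `final` (closing segment), `snapshots`
#'   (equilibrium fitness before each event and at the end), `final_eq`,
#'   `final_fitness`.
#' @export
play_mutation_path <- function(universe, formation, state, script,
                               eps_mut = 1e-3, config = dynamics_config()) {
  stop_if_not_game(universe)
  game <- subgame(universe, formation)
  q <- allelic_state(formation, state)
  steps <- list()
  for (k in seq_along(script)) {
    mut <- script[[k]]
    seg <- segment_run(game, q, config)
    new_game <- expand_game(game, mut$locus, mut$allele, universe)
    cls <- classify_event(game, seg$eq, new_game)
    q <- embed_state(seg$end_state, game$formation, mut$locus, mut$allele,
                     eps_mut)
    game <- new_game
    steps[[k]] <- list(game = seg$game, trajectory = seg$trajectory,
                       locus = mut$locus, allele = mut$allele, class = cls,
                       eq = seg$eq, eq_fitness = seg$eq_fitness)
  }
  closing <- segment_run(game, q, config)
  list(steps = steps, final = closing,
       snapshots = c(vapply(steps, `[[`, numeric(1L), "eq_fitness"),
                     closing$eq_fitness),
       final_eq = closing$eq, final_fitness = closing$eq_fitness)
}

#' Replay a worked scenario
#'
#' Runs the sexual (and, where the scenario contrasts them, asexual)
#' dynamics of an [example_scenario()] and reports the realized outcomes
#' next to the expected labels.
#'
#' @param scenario A `scenario` from [example_scenario()].
#' @param eps_mut Injection frequency for scripted novel mutations (also
#'   used for the asexual genotype injections).
#' @param config Dynamics configuration.
#' @return List with `sexual` (final equilibrium key and fitness),
#'   `asexual` (when contrasted), `expected`, and `matches` (logical).
#' @export
replay_scenario <- function(scenario, eps_mut = 1e-3,
                            config = dynamics_config()) {
  if (!inherits(scenario, "scenario")) stop("expected a `scenario`")
  base <- subgame(scenario$universe, scenario$formation)
  p0 <- scenario$initial_p
  q0 <- allelic_state_of(base, p0)
  out <- list(expected = scenario$expected)

  if (length(scenario$script)) {
    path <- play_mutation_path(scenario$universe, scenario$formation, q0,
                               scenario$script, eps_mut, config)
    out$sexual <- list(final = path$final_eq, fitness = path$final_fitness,
                       snapshots = path$snapshots)
    if (scenario$name == "valley_crossing") {
      # asexual contrast: the mutant genotype joins the genotypic state
      mut <- scenario$script[[1L]]
      game2 <- expand_game(base, mut$locus, mut$allele, scenario$universe)
      p <- numeric(length(game2$fitness))
      names(p) <- names(game2$fitness)
      p[names(p0)] <- p0
      mutg <- game2$genotypes["a1,b1", ]
      mutg[mut$locus] <- mut$allele
      p <- inject_genotype(game2, genotype_state(game2, p),
                           genotype_key(mutg), eps_mut)
      tra <- integrate_to_equilibrium(game2, p, mode = "asexual",
                                      config = config)
      out$asexual <- list(final = tra$limit,
                          fitness = tra$mean_fitness[length(tra$mean_fitness)])
    }
  } else {
    # non-novel script: sexual state unchanged by the event
    trs <- integrate_to_equilibrium(base, q0, mode = "sexual", config = config)
    out$sexual <- list(final = trs$limit,
                       fitness = trs$mean_fitness[length(trs$mean_fitness)])
    if (!is.null(scenario$non_novel)) {
      p <- inject_genotype(base, p0, scenario$non_novel, 1e-6)
      tra <- integrate_to_equilibrium(base, p, mode = "asexual",
                                      config = config)
      out$asexual <- list(final = tra$limit,
                          fitness = tra$mean_fitness[length(tra$mean_fitness)])
    }
  }
  out$matches <- identical(out$sexual$final, scenario$expected$sexual_final) &&
    (is.null(scenario$expected$asexual_final) || is.null(out$asexual) ||
       identical(out$asexual$final, scenario$expected$asexual_final))
  out
}
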