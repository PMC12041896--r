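#' Probability that one mutation arrives before another
#'
#' For independent exponential arrival times with rates `lambda_a` and
#' `lambda_b`, \eqn{\Pr(\tau_a < \tau_b) = \lambda_a / (\lambda_a +
#' \lambda_b)}. This is the probability that the evolutionary path takes the
#' `a`-first branch when two competing novel mutations race; as
#' `lambda_a / lambda_b` tends to 0 the `b`-first branch becomes certain.
#'
#' @param lambda_a,lambda_b Positive rates of the two competing arrivals.
#' @param method `"closed_form"` (default) or `"monte_carlo"` (empirical
#'   frequency over `n` independent exponential pairs; uses the current RNG
#'   state).
#' @param n Number of Monte Carlo pairs.
#' @return `Pr(tau_a < tau_b)` as a scalar in (0, 1).
#' @export
arrival_order_probability <- function(lambda_a, lambda_b,
                                      method = c("closed_form", "monte_carlo"),
                                      n = 1e5) {
  if (!is.numeric(lambda_a) || !is.numeric(lambda_b) ||
      lambda_a <= 0 || lambda_b <= 0)
    stop("both rates must be positive")
  method <- match.arg(method)
  if (method == "closed_form") return(lambda_a / (lambda_a + lambda_b))
  if (n < 1) stop("`n` must be >= 1")
  mean(stats::rexp(n, lambda_a) < stats::rexp(n, lambda_b))
}

#' Hamming distance between genotypes
#'
#' The number of loci at which two genotypes carry different alleles — the
#' minimum number of single-allele substitutions between them.
#'
#' @param g1,g2 Allele vectors of equal length (or genotype keys).
#' @return Non-negative integer.
#' @export
hamming_distance <- function(g1, g2) {
  if (length(g1) == 1L && grepl(",", g1)) g1 <- strsplit(g1, ",")[[1L]]
  if (length(g2) == 1L && grepl(",", g2)) g2 <- strsplit(g2, ",")[[1L]]
  if (length(g1) != length(g2))
    stop("genotypes have different numbers of loci")
  sum(g1 != g2)
}

#' Detect fitness valleys
#'
#' A fitness valley is an ordered pair of local maxima (strict pure Nash
#' genotypes) `g1`, `g2` with (a) `w(g2) > w(g1)`, (b) Hamming distance at
#' least two — so no single substitution bridges them — and (c) no third
#' local maximum on any shortest substitution path between them. In the
#' classical fixed-landscape picture the population cannot cross from `g1`
#' to `g2`; in this model a single Nash-changing mutation can carry a sexual
#' population across.
#'
#' @param game A `ci_game`.
#' @return Data frame with columns `g1`, `g2` (genotype keys), `w_g1`,
#'   `w_g2`, `hamming`, ordered by the genotype enumeration; zero rows when
#'   the landscape has no valley.
#' @export
find_fitness_valleys <- function(game) {
  stop_if_not_game(game)
  nash <- pure_nash(game, strict = TRUE)
  keys <- rownames(nash)
  out <- list()
  if (length(keys) >= 2L) {
    for (i in seq_along(keys)) for (j in seq_along(keys)) {
      if (i == j) next
      g1 <- nash[i, ]; g2 <- nash[j, ]
      if (game$fitness[keys[j]] <= game$fitness[keys[i]]) next
      dh <- hamming_distance(g1, g2)
      if (dh < 2L) next
      blocked <- FALSE
      for (k in seq_along(keys)) {
        if (k == i || k == j) next
        g3 <- nash[k, ]
        if (hamming_distance(g1, g3) + hamming_distance(g3, g2) == dh) {
          blocked <- TRUE; break
        }
      }
      if (!blocked)
        out[[length(out) + 1L]] <- data.frame(
          g1 = keys[i], g2 = keys[j],
          w_g1 = unname(game$fitness[keys[i]]),
          w_g2 = unname(game$fitness[keys[j]]),
          hamming = dh, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(g1 = character(), g2 = character(),
                      w_g1 = numeric(), w_g2 = numeric(),
                      hamming = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Does the order of mutations change the outcome?
#'
#' Plays the same multiset of novel mutations in two orders through the
#' deterministic converge-embed-converge chain ([play_mutation_path()]) and
#' compares the final equilibria. Divergent outcomes exhibit evolutionary
#' contingency: replaying the tape with a different mutation order lands
#' the population on a different fitness peak. Fully deterministic given
#' its inputs.
#'
#' @param universe Master `ci_game`.
#' @param formation Starting formation.
#' @param state Starting allelic state.
#' @param order_a,order_b Lists of `list(locus =, allele =)` events; must
#'   be permutations of the same multiset of mutations.
#' @param eps_mut Injection frequency.
#' @param config Dynamics configuration.
#' @return List with `order_a` and `order_b` (each the
#'   [play_mutation_path()] result plus an event log), `divergent`
#'   (logical: final equilibria differ), and `finals`/`fitness` summaries.
#' @export
compare_contingency <- function(universe, formation, state, order_a, order_b,
                                eps_mut = 1e-3, config = dynamics_config()) {
  sig <- function(ord) sort(vapply(ord, function(e)
    paste(e$locus, e$allele, sep = ":"), character(1L)))
  if (!identical(sig(order_a), sig(order_b)))
    stop("the two orders are not permutations of the same mutation multiset")
  pa <- play_mutation_path(universe, formation, state, order_a, eps_mut, config)
  pb <- play_mutation_path(universe, formation, state, order_b, eps_mut, config)
  list(order_a = pa, order_b = pb,
       finals = c(a = pa$final_eq, b = pb$final_eq),
       fitness = c(a = pa$final_fitness, b = pb$final_fitness),
       divergent = !identical(pa$final_eq, pb$final_eq))
}

# novel candidates of a formation within a universe, with the conditional
# law of the event sampler given that the event is novel:
# P(locus, allele) proportional to (1/m) * (1/|pool_locus|)
novel_candidates <- function(formation, universe) {
  pools <- universe$formation$alleles
  rows <- list()
  for (l in formation$loci) {
    new <- setdiff(pools[[l]], formation$alleles[[l]])
    if (length(new))
      rows[[l]] <- data.frame(locus = l, allele = new,
                              weight = 1 / length(pools[[l]]),
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(locus = character(), allele = character(),
                      prob = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$prob <- out$weight / sum(out$weight)
  out$weight <- NULL
  out
}

# equilibrium fitness reached after adding (locus, allele) to `game` at
# state `q` and letting the flow converge: the small-rate continuation map
continuation_fitness <- function(universe, game, q, locus, allele,
                                 eps_mut, config) {
  new_game <- expand_game(game, locus, allele, universe)
  q2 <- embed_state(q, game$formation, locus, allele, eps_mut)
  traj <- integrate_to_equilibrium(new_game, q2, mode = "sexual",
                                   config = config)
  traj$limit_fitness
}

#' The centered fitness random walk of a run
#'
#' Let \eqn{Y_k} be the equilibrium fitness established by the k-th novel
#' mutation (read in the rare-mutation limit: the fitness of the
#' equilibrium the flow reaches after the mutation is embedded). The
#' centered walk \eqn{Z_k = Z_{k-1} + Y_k - E[Y_k \mid \mathrm{history}]}
#' is a martingale: it accumulates only the unpredictable part of each
#' fitness jump. With \eqn{\sigma_k^2} the conditional variance of the k-th
#' increment, the walk is read off at the first index \eqn{\kappa_v} at
#' which the cumulative conditional variance reaches the budget `v`, and
#' the normalized endpoint \eqn{F = Z_{\kappa_v} / \sqrt{v}} is
#' asymptotically standard normal as `v` grows (martingale CLT). `F`
#' quantifies how unpredictable the replayed tape of life is at a fixed
#' amount of accumulated surprise.
#'
#' Conditional means and variances are estimated at each novel event from
#' the frozen pre-event state by replaying sibling continuations: either a
#' branching Monte Carlo sample of `B` alternative mutations
#' (`estimator = "branching"`) or exact enumeration of the finite candidate
#' pool with its sampling weights (`estimator = "exact"`, available
#' whenever pools are finite).
#'
#' @param run A `pdmp_run`.
#' @param v Positive variance budget.
#' @param estimator `"branching"` or `"exact"`.
#' @param B Number of sibling continuations per event for the branching
#'   estimator (>= 2).
#' @param jump_bound Optional bound `c` on `|Z_k - Z_{k-1}|`; increments
#'   exceeding it trigger a warning.
#' @param eps_mut,config Continuation settings; default to the run's.
#' @return A `fitness_walk`: list with `Y`, `Z`, `sigma2` (computed up to
#'   the first index past the variance budget — later increments cannot
#'   change the normalized endpoint), `v`, `kappa_v` (`NA` when the budget
#'   is never reached), `F` (`NA` likewise), and `n_novel` (novel events in
#'   the run). Uses the current RNG state when `estimator = "branching"`.
#' @export
fitness_walk <- function(run, v, estimator = c("branching", "exact"),
                         B = 20, jump_bound = NULL,
                         eps_mut = NULL, config = NULL) {
  if (!inherits(run, "pdmp_run")) stop("expected a `pdmp_run`")
  if (!is.numeric(v) || v <= 0) stop("`v` must be positive")
  estimator <- match.arg(estimator)
  if (estimator == "branching" && B < 2) stop("`B` must be >= 2")
  if (is.null(eps_mut)) eps_mut <- run$eps_mut
  if (is.null(config)) config <- run$config
  idx <- which(run$events$class != "non_novel")
  K <- length(idx)
  if (K == 0L)
    return(structure(list(Y = numeric(), Z = numeric(), sigma2 = numeric(),
                          v = v, kappa_v = NA_integer_, F = NA_real_,
                          n_novel = 0L), class = "fitness_walk"))
  Y <- numeric(K)
  dZ <- numeric(K)
  sigma2 <- numeric(K)
  # Y_1 is set before the first novel arrival by the deterministic flow of
  # the initial game: its conditional expectation is itself
  Y[1L] <- run$segments[[idx[1L]]]$eq_fitness
  if (K >= 2L) {
    for (k in 2:K) {
      # increments beyond the stopping index cannot affect Z_{kappa_v}
      if (sum(sigma2) >= v) { K <- k - 1L; break }
      j <- idx[k - 1L]
      seg <- run$segments[[j]]
      cand <- novel_candidates(seg$game$formation, run$universe)
      cont <- function(l, a)
        continuation_fitness(run$universe, seg$game, seg$end_state,
                             l, a, eps_mut, config)
      # realized next equilibrium through the same continuation map
      Y[k] <- cont(seg$event$locus, seg$event$allele)
      if (estimator == "exact") {
        ys <- mapply(cont, cand$locus, cand$allele)
        mu <- sum(cand$prob * ys)
        s2 <- sum(cand$prob * (ys - mu)^2)
      } else {
        pick <- sample.int(nrow(cand), B, replace = TRUE, prob = cand$prob)
        ys <- mapply(cont, cand$locus[pick], cand$allele[pick])
        mu <- mean(ys)
        s2 <- stats::var(ys)
      }
      dZ[k] <- Y[k] - mu
      sigma2[k] <- s2
    }
  }
  Y <- Y[seq_len(K)]; dZ <- dZ[seq_len(K)]; sigma2 <- sigma2[seq_len(K)]
  Z <- cumsum(dZ)
  if (!is.null(jump_bound) && any(abs(dZ) > jump_bound))
    warning("walk increment exceeds the configured jump bound")
  cum <- cumsum(sigma2)
  kappa <- which(cum >= v)[1L]
  Fv <- if (is.na(kappa)) NA_real_ else Z[kappa] / sqrt(v)
  structure(list(Y = Y, Z = Z, sigma2 = sigma2, v = v,
                 kappa_v = if (is.na(kappa)) NA_integer_ else kappa,
                 F = Fv, n_novel = length(idx)),
            class = "fitness_walk")
}

#' @export
print.fitness_walk <- function(x, ...) {
  cat(sprintf(
    "fitness walk: %d novel events, total conditional variance %.4g\n",
    x$n_novel, sum(x$sigma2)))
  if (is.na(x$kappa_v))
    cat(sprintf("  variance budget v = %g not reached\n", x$v))
  else
    cat(sprintf("  kappa_v = %d, F = Z/sqrt(v) = %.4g\n", x$kappa_v, x$F))
  invisible(x)
}

#' Fitness-walk statistics over an ensemble of runs
#'
#' Computes [fitness_walk()] for each run and collects the normalized
#' endpoints `F`. Runs whose accumulated conditional variance never reaches
#' the budget `v` are excluded with a warning. Over many independent runs
#' the `F` sample should be centered at 0 with variance near 1 (slightly
#' above, by the overshoot of the variance budget at the stopping index).
#'
#' @param runs List of `pdmp_run` objects (>= 2).
#' @inheritParams fitness_walk
#' @return List with `walks`, `F` (vector over the retained runs), and
#'   `excluded` (indices of excluded runs).
#' @export
fitness_walk_ensemble <- function(runs, v,
                                  estimator = c("branching", "exact"),
                                  B = 20, jump_bound = NULL,
                                  eps_mut = NULL, config = NULL) {
  if (!is.list(runs) || length(runs) < 2L)
    stop("`runs` must be a list of at least two runs")
  estimator <- match.arg(estimator)
  walks <- lapply(runs, fitness_walk, v = v, estimator = estimator, B = B,
                  jump_bound = jump_bound, eps_mut = eps_mut, config = config)
  F <- vapply(walks, `[[`, numeric(1L), "F")
  excluded <- which(is.na(F))
  if (length(excluded))
    warning(sprintf(
      "%d run(s) excluded: accumulated variance below the budget v = %g",
      length(excluded), v))
  list(walks = walks, F = F[!is.na(F)], excluded = excluded)
}
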