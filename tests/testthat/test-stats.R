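test_that("arrival-order probabilities: closed form, symmetry, Monte Carlo", {
  expect_equal(arrival_order_probability(1, 1), 0.5)
  expect_equal(arrival_order_probability(3, 1), 0.75)
  expect_error(arrival_order_probability(-1, 1), "positive")

  # complementary probabilities sum to one
  expect_equal(arrival_order_probability(2.3, 0.7) +
                 arrival_order_probability(0.7, 2.3), 1)

  # as lambda_a / lambda_b tends to 0, Pr(tau_b < tau_a) tends to 1
  ratios <- 10^-(1:8)
  pb <- vapply(ratios, function(r) arrival_order_probability(1, r),
               numeric(1L))
  expect_true(all(diff(pb) > 0))
  expect_equal(pb[8], 1, tolerance = 1e-7)

  set.seed(420)
  for (i in 1:20) {
    la <- runif(1, 0.1, 5); lb <- runif(1, 0.1, 5)
    p <- arrival_order_probability(la, lb)
    pm <- arrival_order_probability(la, lb, method = "monte_carlo", n = 1e5)
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(pm - p), 3 * se + 1e-12)
  }
})

test_that("hamming distance counts differing loci", {
  expect_equal(hamming_distance(c("a1", "b1"), c("a2", "b2")), 2)
  expect_equal(hamming_distance(c("a1", "b1"), c("a1", "b1")), 0)
  expect_equal(hamming_distance("a1,b1", "a1,b2"), 1)
  expect_error(hamming_distance(c("a1"), c("a1", "b1")), "different numbers")
})

test_that("valley detection matches the landscapes and an exhaustive oracle", {
  v1 <- find_fitness_valleys(example_matrix(1, 0.25))
  expect_equal(nrow(v1), 1L)
  expect_equal(v1$g1, "a1,b1")
  expect_equal(v1$g2, "a2,b2")
  expect_equal(v1$hamming, 2L)

  v3 <- find_fitness_valleys(example_matrix(3, 0.25))
  expect_equal(v3$g1, "a2,b2")
  expect_equal(v3$g2, "a3,b1")

  # a single-genotype game has one local maximum, hence no valley
  g0 <- common_interests_game(allelic_formation(list(A = "a", B = "b")), 1)
  expect_equal(nrow(find_fitness_valleys(g0)), 0L)

  set.seed(421)
  for (i in 1:40) {
    g <- random_game(sample(2:3, sample(2:3, 1), replace = TRUE))
    v <- find_fitness_valleys(g)
    got <- sort(paste(v$g1, v$g2, sep = "->"))
    expect_equal(got, oracle_valleys(g))
  }
})

test_that("mutation order changes the outcome exactly when basins differ", {
  m4 <- example_matrix(4, 0.25)
  m1 <- example_matrix(1, 0.25)
  q0 <- allelic_state_of(m1, example_start(m1))
  ord_ab <- list(list(locus = "B", allele = "b3"),
                 list(locus = "A", allele = "a3"))
  ord_ba <- rev(ord_ab)

  cc <- compare_contingency(m4, m1$formation, q0, ord_ab, ord_ba)
  expect_true(cc$divergent)
  expect_equal(unname(cc$finals), c("a2,b2", "a3,b1"))
  expect_equal(unname(cc$fitness), c(2, 3))

  # identical orders cannot diverge, and the comparison is deterministic
  cc2 <- compare_contingency(m4, m1$formation, q0, ord_ab, ord_ab)
  expect_false(cc2$divergent)
  cc3 <- compare_contingency(m4, m1$formation, q0, ord_ab, ord_ba)
  expect_identical(cc$finals, cc3$finals)
  expect_identical(cc$fitness, cc3$fitness)

  expect_error(compare_contingency(m4, m1$formation, q0, ord_ab,
                                   list(list(locus = "B", allele = "b3"))),
               "permutations")

  # additions that never disturb the occupied equilibrium: same final
  set.seed(422)
  uni <- additive_universe(n_loci = 2, pool_size = 3,
                           effect_law = function(n) runif(n, 0.1, 0.9))
  # all novel effects are below the wild type, so every addition is
  # game-changing only
  q0u <- lapply(uni$formation$alleles, function(a) setNames(1, a))
  muts <- list(list(locus = "L1", allele = "L1.m1"),
               list(locus = "L2", allele = "L2.m1"))
  ccu <- compare_contingency(uni$universe, uni$formation, q0u, muts, rev(muts))
  expect_false(ccu$divergent)
  for (s in ccu$order_a$steps) expect_equal(s$class, "game_changing")
})

test_that("the centered fitness walk is degenerate on forced paths", {
  # a universe with a single novel candidate at each step: every
  # continuation is forced, so Y equals its conditional mean and Z stays 0
  m4 <- example_matrix(4, 0.25)
  f1 <- example_matrix(1, 0.25)$formation
  f2 <- expand_formation(f1, "B", "b3")
  uni_b3 <- subgame(m4, f2)  # pool adds only b3
  q0 <- list(A = c(0.995, 0.005), B = c(0.995, 0.005))
  set.seed(423)
  run <- run_pdmp(uni_b3, f1, q0, lambda = 1, n_events = 10,
                  stop_when_exhausted = FALSE)
  wk <- fitness_walk(run, v = 1, estimator = "exact")
  expect_true(all(abs(wk$Z) < 1e-12))
  expect_true(is.na(wk$F))  # no conditional variance accumulates
})

test_that("two equally likely continuations give the two-point variance", {
  # one locus, wild type plus two novel candidates with distinct gains:
  # sigma^2 of the first random step is ((y1 - y2)/2)^2
  f <- allelic_formation(list(L = c("wt", "m1", "m2")))
  uni <- common_interests_game(f, c(wt = 1, m1 = 1.4, m2 = 1.8))
  start <- allelic_formation(list(L = "wt"))
  q0 <- list(L = c(wt = 1))
  set.seed(424)
  run <- run_pdmp(uni, start, q0, lambda = 1, n_events = 6,
                  stop_when_exhausted = FALSE)
  wk <- fitness_walk(run, v = 0.01, estimator = "exact")
  d <- (1.8 - 1.4) / 2
  expect_equal(wk$sigma2[2], d^2, tolerance = 1e-9)
  expect_equal(wk$kappa_v, 2L)
  # the realized increment is +/- d
  expect_equal(abs(wk$Z[2] - wk$Z[1]), d, tolerance = 1e-9)
})

test_that("branching estimates center the walk increments", {
  set.seed(425)
  au <- additive_universe(n_loci = 3, pool_size = 4)
  q0 <- lapply(au$formation$alleles, function(a) setNames(1, a))
  cfg <- dynamics_config(horizon = 2000, n_grid = 40)
  incs <- c()
  for (r in 1:12) {
    run <- run_pdmp(au$universe, au$formation, q0, lambda = 1, n_events = 15,
                    config = cfg)
    wk <- fitness_walk(run, v = 0.05, estimator = "branching", B = 12,
                       config = cfg)
    incs <- c(incs, diff(c(0, wk$Z)))
  }
  # increments conditioned on their branch histories are mean-zero up to
  # estimator noise
  expect_lt(abs(mean(incs)), 4 * stats::sd(incs) / sqrt(length(incs)))
})
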