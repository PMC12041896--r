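test_that("replicator fields match hand-computed values and conserve mass", {
  g <- example_matrix(1, 0.25)
  # vertices are fixed points
  p_mono <- genotype_state(g, c("a1,b1" = 1, "a1,b2" = 0, "a2,b1" = 0,
                                "a2,b2" = 0))
  expect_equal(unname(replicator_field(g, p_mono)), rep(0, 4))
  q_pt <- allelic_state(g, list(A = c(1, 0), B = c(0, 1)))
  expect_equal(unlist(multireplicator_field(g, q_pt), use.names = FALSE),
               rep(0, 4))

  # two-genotype hand example: w = (1, 2), p = (0.5, 0.5)
  g2 <- common_interests_game(allelic_formation(list(L = c("x", "y"))),
                              c(1, 2))
  expect_equal(unname(replicator_field(g2, c(0.5, 0.5))), c(-0.25, 0.25))

  # uniform allelic state on the 2x2 landscape
  q_u <- allelic_state(g, list(A = c(0.5, 0.5), B = c(0.5, 0.5)))
  fld <- multireplicator_field(g, q_u)
  expect_equal(unname(fld$A["a1"]), -0.125)

  set.seed(405)
  for (i in 1:10) {
    gg <- random_game(c(3, 3, 2))
    p <- random_interior_state(gg, "asexual")
    expect_equal(sum(replicator_field(gg, p)), 0, tolerance = 1e-12)
    q <- random_interior_state(gg, "sexual")
    for (v in multireplicator_field(gg, q))
      expect_equal(sum(v), 0, tolerance = 1e-12)
  }
})

test_that("the compiled flow matches a reference integrator and closed form", {
  skip_if_not_installed("deSolve")
  g <- example_matrix(1, 0.25)
  p0 <- example_start(g)
  q0 <- allelic_state_of(g, p0)

  # sexual flow vs deSolve on the same R-side field
  cfg <- dynamics_config(horizon = 5, n_grid = 6)
  tr <- integrate_to_equilibrium(g, q0, "sexual", config = cfg)
  ref <- ref_integrate(g, q0, "sexual", times = tr$times)
  for (r in seq_along(tr$times))
    expect_equal(unname(tr$states[r, ]), unname(ref[r, -1]), tolerance = 1e-6)

  # asexual flow has a closed form: p(t) proportional to p0 exp(w t)
  tra <- integrate_to_equilibrium(g, p0, "asexual", config = cfg)
  for (r in seq_along(tra$times))
    expect_equal(unname(tra$states[r, ]),
                 unname(asex_closed_form(g, p0, tra$times[r])),
                 tolerance = 1e-8)
})

test_that("flows converge to the worked-example equilibria", {
  g1 <- example_matrix(1, 0.25)
  q0 <- allelic_state_of(g1, example_start(g1))

  tr1 <- integrate_to_equilibrium(g1, q0, "sexual")
  expect_true(tr1$converged)
  expect_equal(tr1$limit, "a1,b1")
  expect_equal(tail(tr1$mean_fitness, 1), 1, tolerance = 1e-3)

  # expanded landscape: the occupied equilibrium is destroyed and the
  # population crosses to (a2,b2); the triggering allele b3 goes extinct
  g2 <- example_matrix(2, 0.25)
  q1 <- embed_state(q0, g1$formation, "B", "b3", 1e-3)
  tr2 <- integrate_to_equilibrium(g2, q1, "sexual")
  expect_true(tr2$converged)
  expect_equal(tr2$limit, "a2,b2")
  expect_equal(tail(tr2$mean_fitness, 1), 2, tolerance = 1e-3)
  expect_lt(tr2$final_state$B["b3"], 1e-6)

  # starting exactly at a strict Nash vertex, the flow stays put
  q_nash <- allelic_state(g1, list(A = c(0, 1), B = c(0, 1)))
  tr3 <- integrate_to_equilibrium(g1, q_nash, "sexual")
  expect_true(tr3$converged)
  expect_equal(tr3$velocity_norm, 0)
  expect_equal(tr3$limit, "a2,b2")
  expect_false(tr3$interior)
})

test_that("mean fitness is non-decreasing along integrated trajectories", {
  set.seed(406)
  for (i in 1:10) {
    g <- random_game(c(3, 2, 2))
    trs <- integrate_to_equilibrium(g, random_interior_state(g, "sexual"),
                                    "sexual")
    expect_true(all(diff(trs$mean_fitness) >= -1e-8))
    tra <- integrate_to_equilibrium(g, random_interior_state(g, "asexual"),
                                    "asexual")
    expect_true(all(diff(tra$mean_fitness) >= -1e-8))
  }
})

test_that("interior starts reach strict Nash (sexual) and the optimum (asexual)", {
  set.seed(407)
  cfg <- dynamics_config(horizon = 1e6)
  for (i in 1:10) {
    g <- random_game(sample(2:3, sample(2:3, 1), replace = TRUE))
    strict <- rownames(pure_nash(g))
    best <- names(which.max(g$fitness))
    for (j in 1:5) {
      trs <- integrate_to_equilibrium(g, random_interior_state(g, "sexual"),
                                      "sexual", config = cfg)
      expect_true(trs$converged)
      expect_true(trs$limit %in% strict)
      tra <- integrate_to_equilibrium(g, random_interior_state(g, "asexual"),
                                      "asexual", config = cfg)
      expect_true(tra$converged)
      expect_equal(tra$limit, best)
    }
  }
})

test_that("distance to the Nash set behaves like an L1 point-to-set distance", {
  g <- example_matrix(1, 0.25)
  expect_equal(distance_to_nash(g, list(A = c(1, 0), B = c(1, 0))), 0)
  expect_equal(distance_to_nash(g, list(A = c(0.9, 0.1), B = c(1, 0))), 0.2)
  # bounded by twice the number of loci
  set.seed(408)
  for (i in 1:20) {
    q <- random_interior_state(g, "sexual")
    d <- distance_to_nash(g, q)
    expect_gte(d, 0)
    expect_lte(d, 4)
  }
})

test_that("the multi-replicator is a Shahshahani gradient of mean fitness", {
  set.seed(409)
  for (i in 1:25) {
    g <- random_game(c(2, 2))
    q <- random_interior_state(g, "sexual")
    expect_lt(shahshahani_residual(g, q, h = 1e-5), 1e-6)
    # ascent: the directional derivative of w along the field is >= 0
    fld <- multireplicator_field(g, q)
    marg <- lapply(g$formation$loci, function(l)
      vapply(g$formation$alleles[[l]], function(a)
        marginal_fitness(g, q, l, a), numeric(1L)))
    dirderiv <- sum(unlist(fld) * unlist(marg))
    expect_gte(dirderiv, -1e-12)
  }
  # near-vertex interior points keep the gradient property
  g <- example_matrix(1, 0.25)
  q <- allelic_state(g, list(A = c(1 - 1e-4, 1e-4), B = c(1 - 1e-4, 1e-4)))
  expect_lt(shahshahani_residual(g, q, h = 1e-6), 1e-5)
  expect_error(shahshahani_residual(g, list(A = c(1, 0), B = c(1, 0))),
               "interior")
})
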