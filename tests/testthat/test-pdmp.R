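test_that("waiting times are exponential and the sampler is reproducible", {
  m4 <- example_matrix(4, 0.25)
  f <- example_matrix(1, 0.25)$formation
  set.seed(410)
  waits <- replicate(1e5, sample_next_event(f, m4, lambda = 2)$wait)
  # exponential(2): mean 1/2, sd 1/2; allow 3 standard errors
  expect_equal(mean(waits), 0.5, tolerance = 3 * 0.5 / sqrt(1e5) / 0.5)

  # a pool equal to the current formation only yields non-novel events
  m1 <- example_matrix(1, 0.25)
  set.seed(411)
  evs <- replicate(200, sample_next_event(f, m1, lambda = 1)$novel)
  expect_false(any(evs))

  set.seed(412)
  e1 <- replicate(20, sample_next_event(f, m4, 1), simplify = FALSE)
  set.seed(412)
  e2 <- replicate(20, sample_next_event(f, m4, 1), simplify = FALSE)
  expect_identical(e1, e2)
})

test_that("embedding injects the new allele and preserves the simplices", {
  f <- allelic_formation(list(A = c("a1", "a2"), B = c("b1", "b2")))
  q <- allelic_state(f, list(A = c(0.6, 0.4), B = c(0.99, 0.01)))
  q2 <- embed_state(q, f, "B", "b3", 1e-3)
  expect_equal(unname(q2$B), c(0.98901, 0.00999, 0.001))
  expect_equal(unname(q2$A), c(0.6, 0.4))
  expect_equal(sum(q2$B), 1, tolerance = 1e-15)

  # shrinking the injection recovers the embedded face
  q3 <- embed_state(q, f, "B", "b3", 1e-12)
  expect_equal(unname(q3$B[1:2]), unname(q$B), tolerance = 1e-9)

  expect_error(embed_state(q, f, "B", "b3", 0), "strictly between")
  expect_error(embed_state(q, f, "B", "b1", 1e-3),
               class = "nashevol_non_novel")
})

test_that("events are classified by the fate of the occupied equilibrium", {
  m1 <- example_matrix(1, 0.25)
  m2 <- example_matrix(2, 0.25)
  m4 <- example_matrix(4, 0.25)

  # adding b3 destroys (a1,b1): Nash-changing
  expect_equal(classify_event(m1, "a1,b1", m2), "nash_changing")
  # adding a3 to the 2x3 game leaves (a2,b2) in place: game-changing only
  g24 <- expand_game(m2, "A", "a3", m4)
  expect_equal(classify_event(m2, "a2,b2", g24), "game_changing")
  # identical formations: non-novel
  expect_equal(classify_event(m1, "a1,b1", m1), "non_novel")
  # the occupied state must be an equilibrium of the old game
  expect_error(classify_event(m1, "a1,b2", m2), "not a pure Nash")
})

test_that("scripted paths reproduce the two worked mutation chains", {
  m4 <- example_matrix(4, 0.25)
  m1 <- example_matrix(1, 0.25)
  q0 <- allelic_state_of(m1, example_start(m1))

  ab <- play_mutation_path(m4, m1$formation, q0,
                           list(list(locus = "B", allele = "b3"),
                                list(locus = "A", allele = "a3")))
  expect_equal(ab$snapshots, c(1, 2, 2))
  expect_equal(ab$final_eq, "a2,b2")
  expect_equal(vapply(ab$steps, `[[`, character(1L), "class"),
               c("nash_changing", "game_changing"))

  ba <- play_mutation_path(m4, m1$formation, q0,
                           list(list(locus = "A", allele = "a3"),
                                list(locus = "B", allele = "b3")))
  expect_equal(ba$snapshots, c(1, 3, 3))
  expect_equal(ba$final_eq, "a3,b1")
})

test_that("PDMP runs are seed-reproducible and fitness-monotone", {
  m4 <- example_matrix(4, 0.25)
  f1 <- example_matrix(1, 0.25)$formation
  q0 <- list(A = c(0.995, 0.005), B = c(0.995, 0.005))

  set.seed(413)
  r1 <- run_pdmp(m4, f1, q0, lambda = 0.05, n_events = 12,
                 stop_when_exhausted = FALSE)
  set.seed(413)
  r2 <- run_pdmp(m4, f1, q0, lambda = 0.05, n_events = 12,
                 stop_when_exhausted = FALSE)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$final_state, r2$final_state)

  # consecutive games along the run are linked by identity or one edge
  forms <- lapply(r1$segments, function(s) s$game$formation)
  for (k in seq_len(length(forms) - 1L)) {
    same <- identical(forms[[k]], forms[[k + 1L]])
    expect_true(same || is_expansion_edge(forms[[k]], forms[[k + 1L]])$is_edge)
  }

  sn <- equilibrium_snapshots(r1)
  expect_true(all(diff(sn) >= 0))
  inc <- diff(sn)
  expect_equal(inc > 1e-9, r1$events$class == "nash_changing")
})

test_that("classification is sound across seeded random-universe runs", {
  set.seed(414)
  for (rep in 1:10) {
    uni <- random_game(c(3, 3))
    start <- allelic_formation(lapply(uni$formation$alleles, function(a) a[1:2]))
    q0 <- lapply(start$alleles, function(a) setNames(rep(0.5, 2), a))
    run <- run_pdmp(uni, start, q0, lambda = 0.02, n_events = 8)
    # Nash-changing events are exactly those whose post equilibrium differs
    novel <- run$events$class != "non_novel"
    moved <- run$events$pre_eq != run$events$post_eq
    expect_equal(run$events$class == "nash_changing", novel & moved)
    expect_true(all(diff(equilibrium_snapshots(run)) >= 0))
  }
})
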