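test_that("genotype enumeration is a stable lexicographic product", {
  f <- allelic_formation(list(A = c("a1", "a2"), B = c("b1", "b2")))
  gm <- enumerate_genotypes(f)
  expect_equal(rownames(gm), c("a1,b1", "a1,b2", "a2,b1", "a2,b2"))
  expect_identical(gm, enumerate_genotypes(f))

  f1 <- allelic_formation(list(A = "a1"))
  expect_equal(rownames(enumerate_genotypes(f1)), "a1")

  f23 <- allelic_formation(list(A = c("a1", "a2"), B = c("b1", "b2", "b3")))
  expect_equal(nrow(enumerate_genotypes(f23)), 6L)
})

test_that("formation and state validation reject malformed input", {
  expect_error(allelic_formation(list(c("a1", "a2"))), "name")
  expect_error(allelic_formation(list(A = c("a1", "a1"))), "unique")
  expect_error(allelic_formation(list(A = character(0))), "no alleles")

  g <- example_matrix(1)
  expect_error(genotype_state(g, c(0.5, 0.5, 0.1, 0)), "sum to 1")
  expect_error(genotype_state(g, c(-0.1, 0.6, 0.5, 0)), "non-negative")
  expect_error(allelic_state(g, list(A = c(0.7, 0.7), B = c(1, 0))), "sum to 1")
  expect_error(common_interests_game(g$formation, c(1, 2, 3, -1)), "positive")
  expect_error(common_interests_game(g$formation, c("a1,b1" = 1)), "missing")
})

test_that("mean fitness functionals reproduce the worked 2x2 landscape", {
  g <- example_matrix(1, delta = 0.25)
  # monomorphic (a2,b2) has the matrix's corner fitness
  p_mono <- genotype_state(g, c("a1,b1" = 0, "a1,b2" = 0, "a2,b1" = 0, "a2,b2" = 1))
  expect_equal(mean_fitness_genotypic(g, p_mono), 2)
  expect_equal(mean_fitness_genotypic(g, rep(0.25, 4)), 0.875)

  q_pt <- allelic_state(g, list(A = c(0, 1), B = c(0, 1)))
  expect_equal(mean_fitness_allelic(g, q_pt), 2)
  q_u <- allelic_state(g, list(A = c(0.5, 0.5), B = c(0.5, 0.5)))
  expect_equal(mean_fitness_allelic(g, q_u), 0.875)

  expect_equal(marginal_fitness(g, list(A = c(1, 0), B = c(1, 0)), "A", "a1"), 1)
  expect_equal(marginal_fitness(g, q_u, "A", "a1"), 0.625)
  expect_error(marginal_fitness(g, q_u, "A", "zz"), "unknown allele")
})

test_that("allelic marginals of a genotypic state sum correctly", {
  g <- example_matrix(1)
  p <- genotype_state(g, c("a1,b1" = 1, "a1,b2" = 0, "a2,b1" = 0, "a2,b2" = 0))
  q <- allelic_state_of(g, p)
  expect_equal(unname(q$A), c(1, 0))
  expect_equal(unname(q$B), c(1, 0))

  p2 <- example_start(g, eps = 0.01)
  q2 <- allelic_state_of(g, p2)
  expect_equal(unname(q2$A), c(0.995, 0.005))
  expect_equal(unname(q2$B), c(0.995, 0.005))

  q3 <- allelic_state_of(g, rep(0.25, 4))
  expect_equal(unname(q3$A), c(0.5, 0.5))
})

test_that("allelic and genotypic mean fitness agree under product states", {
  set.seed(401)
  for (i in 1:20) {
    shape <- sample(2:3, sample(2:3, 1), replace = TRUE)
    g <- random_game(shape)
    q <- random_interior_state(g, "sexual")
    # product distribution induced by q
    p <- apply(g$genotypes, 1L, function(row)
      prod(vapply(seq_along(row), function(i) q[[i]][row[i]], numeric(1L))))
    expect_equal(mean_fitness_allelic(g, q),
                 mean_fitness_genotypic(g, p / sum(p)),
                 tolerance = 1e-12)
    # envelope identity: frequency-weighted marginals average to the mean
    for (l in g$formation$loci) {
      marg <- vapply(g$formation$alleles[[l]], function(a)
        marginal_fitness(g, q, l, a), numeric(1L))
      expect_equal(sum(q[[l]] * marg), mean_fitness_allelic(g, q),
                   tolerance = 1e-10)
    }
  }
})

test_that("marginal fitness is the partial derivative of mean fitness", {
  set.seed(402)
  h <- 1e-6
  g <- random_game(c(3, 2, 2))
  q <- random_interior_state(g, "sexual")
  qf <- unlist(q, use.names = FALSE)
  off <- 0L
  for (l in g$formation$loci) {
    for (j in seq_along(g$formation$alleles[[l]])) {
      e <- numeric(length(qf)); e[off + j] <- h
      fd <- (nashevol:::mean_fitness_allelic_raw(g, qf + e) -
             nashevol:::mean_fitness_allelic_raw(g, qf - e)) / (2 * h)
      expect_equal(marginal_fitness(g, q, l, g$formation$alleles[[l]][j]),
                   fd, tolerance = 1e-6)
    }
    off <- off + length(g$formation$alleles[[l]])
  }
})

test_that("pure Nash enumeration matches the worked landscapes and an oracle", {
  expect_equal(rownames(pure_nash(example_matrix(1, 0.25))),
               c("a1,b1", "a2,b2"))
  expect_equal(rownames(pure_nash(example_matrix(2, 0.25))), "a2,b2")
  expect_equal(rownames(pure_nash(example_matrix(3, 0.25))),
               c("a2,b2", "a3,b1"))
  # the 3x3 landscape has a fitness tie making (a1,b3) weak but not strict
  m4 <- example_matrix(4, 0.25)
  expect_equal(rownames(pure_nash(m4, strict = TRUE)), c("a2,b2", "a3,b1"))
  expect_equal(rownames(pure_nash(m4, strict = FALSE)),
               c("a1,b3", "a2,b2", "a3,b1"))

  # single-locus game: the argmax allele is the only equilibrium
  g1 <- common_interests_game(allelic_formation(list(L = c("x", "y", "z"))),
                              c(0.5, 2, 1))
  expect_equal(rownames(pure_nash(g1)), "y")

  set.seed(403)
  for (i in 1:100) {
    shape <- sample(2:3, sample(1:3, 1), replace = TRUE)
    g <- random_game(shape)
    expect_equal(rownames(pure_nash(g, strict = TRUE)),
                 oracle_nash(g, strict = TRUE))
    expect_equal(rownames(pure_nash(g, strict = FALSE)),
                 oracle_nash(g, strict = FALSE))
  }
})
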