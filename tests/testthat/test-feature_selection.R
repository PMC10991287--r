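sim_xy <- function(n = 120, p = 6, seed = 1) {
  g <- gen_tabular(tabular_spec(n = n, p = p, n_informative = 2,
                                effect_size = 2, seed = seed))
  list(X = g$X, y = g$y)
}

test_that("genome fitness is seeded-deterministic, mask-faithful, Inf on empty masks", {
  d <- sim_xy()
  full <- rep(TRUE, ncol(d$X))
  f1 <- genome_fitness(full, d$X, d$y, seed = 9)
  f2 <- genome_fitness(full, d$X, d$y, seed = 9)
  expect_identical(f1, f2)
  expect_true(is.finite(f1))
  expect_identical(genome_fitness(rep(FALSE, ncol(d$X)), d$X, d$y), Inf)
  # informative-only mask beats noise-only mask
  info <- c(TRUE, TRUE, rep(FALSE, ncol(d$X) - 2))
  expect_lt(genome_fitness(info, d$X, d$y, seed = 9),
            genome_fitness(!info, d$X, d$y, seed = 9))
})

test_that("elite selection takes the lowest MSE with stable tie-breaks", {
  pop <- list(list(mask = 1, fitness = 3), list(mask = 2, fitness = 1),
              list(mask = 3, fitness = 2), list(mask = 4, fitness = 1))
  top2 <- select_elites(pop, 2)
  expect_equal(vapply(top2, `[[`, numeric(1), "fitness"), c(1, 1))
  expect_equal(vapply(top2, `[[`, numeric(1), "mask"), c(2, 4))
  expect_length(select_elites(pop, 4), 4L)
  expect_error(select_elites(pop, 5), "more elites")
})

test_that("crossover respects its rate and swaps single-point segments", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  b <- !a
  expect_identical(crossover_genomes(a, b, rate = 0, seed = 1),
                   list(a, b))
  ident <- crossover_genomes(a, a, rate = 1, seed = 3)
  expect_identical(ident[[1]], a)
  expect_identical(ident[[2]], a)
  kids <- crossover_genomes(a, b, rate = 1, seed = 5)
  cut <- hdpm:::with_seed(5, { runif(1); sample.int(5, 1) })
  expect_identical(kids[[1]], c(a[1:cut], b[-(1:cut)]))
  expect_identical(kids[[2]], c(b[1:cut], a[-(1:cut)]))
  expect_error(crossover_genomes(a, b[-1], 0.5), "lengths")
})

test_that("mutation flips bits at the configured rate", {
  m <- rep(FALSE, 20)
  expect_identical(mutate_genome(m, 0, seed = 1), m)
  expect_identical(mutate_genome(m, 1, seed = 1), !m)
  flips <- hdpm:::with_seed(11, {
    mean(replicate(2000, sum(mutate_genome(m, 0.05))))
  })
  expect_equal(flips, 0.05 * 20, tolerance = 0.1)
})

test_that("GA history never increases and a zero-generation run returns the initial best", {
  d <- sim_xy(seed = 3)
  res0 <- ga_select(d$X, d$y, ga_config(generations = 0, population = 10,
                                        elites = 5, randoms = 5, seed = 2))
  expect_length(res0$history, 1L)
  res <- ga_select(d$X, d$y, ga_config(generations = 6, population = 16,
                                       elites = 8, randoms = 8, seed = 2))
  expect_true(all(diff(res$history) <= 0))
  expect_equal(res$fitness, min(res$history))
})

test_that("a frozen GA (no operators, all elites) keeps the population set", {
  d <- sim_xy(seed = 4)
  cfg <- ga_config(generations = 3, population = 8, elites = 8,
                   randoms = 0, crossover_rate = 0, mutation_rate = 0,
                   seed = 5)
  res <- ga_select(d$X, d$y, cfg)
  expect_equal(res$history, rep(res$history[1], 4))
})

test_that("RFE keeps the requested count and finds the planted signal", {
  d <- sim_xy(seed = 6)
  expect_setequal(rfe_select(d$X, d$y, rfe_config(ncol(d$X))),
                  colnames(d$X))
  expect_error(rfe_select(d$X, d$y, rfe_config(ncol(d$X) + 1)), "exceeds")

  # one near-copy of the label among pure noise
  set.seed(7)
  X <- cbind(matrix(rnorm(100 * 9), 100, 9), sig = 0)
  colnames(X) <- c(paste0("noise", 1:9), "sig")
  y <- rep(0:1, 50)
  X[, "sig"] <- y + rnorm(100, sd = 0.01)
  expect_identical(as.character(rfe_select(X, y, rfe_config(1))), "sig")
})

test_that("hybrid selection returns an RFE-refined subset of the GA winner", {
  d <- sim_xy(seed = 8)
  ga_cfg <- ga_config(generations = 4, population = 16, elites = 8,
                      randoms = 8, seed = 8)
  res <- hybrid_select(d$X, d$y, ga_cfg, rfe_config(2))
  expect_length(res$features, 2L)
  expect_true(all(res$features %in% res$ga$features))
  same <- hybrid_select(d$X, d$y, ga_cfg,
                        rfe_config(length(res$ga$features)))
  expect_setequal(same$features, res$ga$features)
  expect_error(
    hybrid_select(d$X, d$y, ga_cfg, rfe_config(ncol(d$X) + 1)),
    "GA-selected")
})
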