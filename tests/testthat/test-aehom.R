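test_that("clan and matriarch updates follow the position algebra", {
  p <- c(0, 0); best <- c(2, 2)
  expect_equal(clan_update(p, best, c = 0, r_d = 1), p)
  expect_equal(clan_update(best, best, c = 1, r_d = 1), best)
  expect_equal(clan_update(p, best, c = 1, r_d = 1), best)
  expect_equal(clan_update(p, best, c = 0.5, r_d = 0.5), c(0.5, 0.5))
  expect_equal(clan_update(p, c(10, 10), c = 1, r_d = 1,
                           lower = -5, upper = 5), c(5, 5))
  expect_error(clan_update(p, c(1, 2, 3), 0.5, 1), "mismatch")

  z <- rbind(c(1, 2), c(1, 2))
  expect_equal(matriarch_update(z, l = 1), c(1, 2))
  clan <- rbind(c(0, 0), c(2, 2))
  expect_equal(matriarch_update(clan, l = 0.5), c(0.5, 0.5))
  expect_error(matriarch_update(clan[0, , drop = FALSE], 1), "empty")
})

test_that("worst-member separation redraws within bounds", {
  clan <- matrix(0, nrow = 5, ncol = 4)
  fit <- c(5, 1, 4, 2, 3)
  out <- separate_worst(clan, fit, 2, lower = -2, upper = 3, seed = 1)
  expect_equal(out[c(2, 4, 5), ], clan[c(2, 4, 5), ])  # best kept
  expect_true(all(out >= -2 & out <= 3))
  expect_false(all(out[1, ] == 0))
  expect_error(separate_worst(clan, fit, 5, -1, 1), "whole clan")

  draws <- hdpm:::with_seed(2, replicate(500,
    separate_worst(clan, fit, 1, lower = -2, upper = 3)[1, ]))
  expect_true(all(draws >= -2 & draws <= 3))
})

test_that("two-point crossover exchanges the fixed dimension-derived segment", {
  p1 <- 1:12; p2 <- 101:112
  kids <- crossover_positions(p1, p2)
  seg <- 5:10  # 0-based [4, 10) from L = 12
  expect_equal(kids[[1]][seg], p2[seg])
  expect_equal(kids[[1]][-seg], p1[-seg])
  expect_equal(kids[[2]][seg], p1[seg])
  expect_equal(kids[[2]][-seg], p2[-seg])
  same <- crossover_positions(p1, p1)
  expect_equal(same[[1]], same[[2]])
  expect_error(crossover_positions(1:5, 6:10), "at least 6")
})

test_that("position mutation redraws genes at the configured rate within bounds", {
  p <- rep(0, 50)
  expect_equal(mutate_position(p, 0, -1, 1, seed = 1), p)
  m1 <- mutate_position(p, 1, -1, 1, seed = 1)
  expect_true(all(m1 != 0) && all(m1 >= -1 & m1 <= 1))
  hits <- hdpm:::with_seed(3, {
    mean(replicate(1000, sum(mutate_position(p, 0.1, -1, 1) != 0)))
  })
  expect_equal(hits, 5, tolerance = 0.5)
})

test_that("the optimizer is elitist, bound-respecting and converges on the sphere", {
  sphere <- function(p) sum(p^2)
  cfg0 <- herd_config(dims = 5, lower = -5, upper = 5, generations = 0,
                      seed = 1)
  r0 <- aehom_optimize(sphere, cfg0)
  expect_length(r0$history, 0L)
  expect_true(is.finite(r0$value))

  cfg <- herd_config(dims = 5, lower = -5, upper = 5, generations = 40,
                     seed = 2)
  res <- aehom_optimize(sphere, cfg)
  expect_true(all(diff(res$history) <= 0))
  expect_true(all(res$herd$P >= -5 & res$herd$P <= 5))
  expect_lt(res$value, r0$value)
})

test_that("a frozen herd moves only its matriarchs", {
  cfg <- herd_config(dims = 3, lower = -1, upper = 1, n_clans = 2,
                     clan_size = 4, c = 0, l = 0.5, n_worst = 0,
                     generations = 1, mutation_rate = 0, seed = 4)
  herd0 <- hdpm:::with_seed(9, hdpm:::new_herd(cfg))
  res <- aehom_optimize(function(p) sum(p^2), cfg, herd = herd0)
  moved <- rowSums(res$herd$P != herd0$P) > 0
  expect_lte(sum(moved), cfg$n_clans)
})

test_that("AEHOM training decodes best weights and degrades gracefully to backprop", {
  blobs <- make_blobs(n = 60, sep = 4, seed = 5)
  net_cfg <- network_config(c(2, 4, 1), epochs = 10, seed = 6)
  herd_cfg <- herd_config(dims = n_network_params(c(2, 4, 1)),
                          generations = 10, seed = 6)
  res <- aehom_optimize(function(theta)
    mean((blobs$y - hdpm:::network_raw(
      decode_network(theta, c(2, 4, 1)), blobs$X))^2), herd_cfg)
  trained <- train_network_aehom(net_cfg, blobs$X, blobs$y, herd_cfg)
  expect_s3_class(trained$net, "mldcnn")
  expect_true(all(diff(trained$history) <= 0))

  pure_cfg <- herd_config(dims = n_network_params(c(2, 4, 1)),
                          generations = 0, seed = 6)
  pure <- train_network_aehom(net_cfg, blobs$X, blobs$y, pure_cfg)
  oracle <- train_backprop(init_network(net_cfg), blobs$X, blobs$y,
                           net_cfg)
  expect_equal(pure$net$layers, oracle$net$layers, tolerance = 1e-12)
  expect_length(pure$history, 0L)

  expect_error(train_network_aehom(net_cfg, blobs$X, blobs$y,
                                   herd_config(dims = 3, seed = 1)),
               "parameter count")
})

test_that("metaheuristic initialization does not hurt training MSE on separable data", {
  worse <- 0
  for (s in 1:5) {
    blobs <- make_blobs(n = 60, sep = 4, seed = 100 + s)
    net_cfg <- network_config(c(2, 4, 1), epochs = 15, seed = s)
    herd_cfg <- herd_config(dims = n_network_params(c(2, 4, 1)),
                            generations = 15, seed = s)
    with_aehom <- train_network_aehom(net_cfg, blobs$X, blobs$y, herd_cfg)
    random_init <- train_backprop(init_network(net_cfg), blobs$X,
                                  blobs$y, net_cfg)
    mse <- function(net) mean((blobs$y -
                                 hdpm:::network_raw(net, blobs$X))^2)
    if (mse(with_aehom$net) > mse(random_init$net)) worse <- worse + 1
  }
  expect_lte(worse, 2)
})
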