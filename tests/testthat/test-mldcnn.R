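test_that("activation and weighted-sum primitives match closed forms", {
  expect_equal(gaussian(0), 1)
  expect_equal(gaussian(1), exp(-1), tolerance = 1e-9)
  x <- seq(-3, 3, by = 0.5)
  expect_equal(gaussian(x), gaussian(-x))
  expect_true(all(gaussian(x) > 0 & gaussian(x) <= 1))

  expect_equal(weighted_sum(c(1, 2), c(0.5, 0.5)), 1.5)
  expect_equal(weighted_sum(1:3, rep(0, 3)), 0)
  expect_equal(weighted_sum(1, -2), -2)
  expect_error(weighted_sum(1:2, 1:3), "length")
})

test_that("hand-traced forward passes match the layer equations", {
  cfg <- network_config(c(1, 1, 1), seed = 1)
  net <- init_network(cfg)
  net$layers[[1]]$W[] <- 0; net$layers[[1]]$b[] <- 0
  net$layers[[2]]$W[] <- 0; net$layers[[2]]$b[] <- 0
  fw <- forward(net, 5)
  expect_equal(fw$trace$act[[2]], 1)   # gaussian(0)
  expect_equal(fw$output, 0)

  net$layers[[1]]$W[] <- 1; net$layers[[2]]$W[] <- 1
  expect_equal(forward(net, 0)$output, 1)  # gaussian(0) * 1
  expect_error(forward(net, c(1, 2)), "width")
})

test_that("forward agrees with a per-unit loop oracle on random nets", {
  for (s in 1:100) {
    net <- random_network(s)
    x <- hdpm:::with_seed(1000 + s, rnorm(net$sizes[1]))
    expect_equal(forward(net, x)$output, forward_oracle(net, x),
                 tolerance = 1e-12)
  }
})

test_that("error signals and weight deltas follow the delta rule", {
  expect_equal(output_error(1, 0.8), 0.2)
  expect_equal(output_error(0.3, 0.3), 0)
  expect_equal(output_error(0, 1), -1)

  expect_equal(error_signal(0.2, u = 0.7, unit = "linear"), 0.2)
  expect_equal(error_signal(0, u = 2, unit = "gaussian"), 0)
  expect_equal(error_signal(0.5, u = 0, unit = "gaussian"), 0)
  expect_equal(error_signal(1, u = 1, unit = "gaussian"),
               -2 * exp(-1), tolerance = 1e-12)

  expect_equal(weight_delta(0, 3, 2), 0)
  expect_equal(weight_delta(0.5, 0, 2), 0)
  expect_equal(weight_delta(0.5, 0.2, 1), 0.1)
})

test_that("a small-step online update never increases that sample's error", {
  for (s in 1:30) {
    net <- random_network(s)
    x <- hdpm:::with_seed(2000 + s, rnorm(net$sizes[1]))
    d <- s %% 2
    before <- (d - forward(net, x)$output)^2
    net2 <- hdpm:::backprop_step(net, x, d, alpha = 1e-3)
    after <- (d - forward(net2, x)$output)^2
    expect_lte(after, before + 1e-12)
  }
})

test_that("training is epoch-faithful and learns separable blobs", {
  blobs <- make_blobs(n = 80, sep = 4, seed = 1)
  cfg0 <- network_config(c(2, 4, 1), epochs = 0, seed = 1)
  net <- init_network(cfg0)
  out <- train_backprop(net, blobs$X, blobs$y, cfg0)
  expect_identical(out$net, net)
  expect_length(out$loss, 0L)

  cfg <- network_config(c(2, 6, 1), alpha = 0.05, epochs = 120, seed = 2)
  tr <- train_backprop(init_network(cfg), blobs$X, blobs$y, cfg)
  expect_gte(mean(predict(tr$net, blobs$X) == blobs$y), 0.95)
})

test_that("prediction applies the >= threshold rule", {
  net <- init_network(network_config(c(1, 1, 1), seed = 3))
  net$layers[[1]]$W[] <- 0; net$layers[[1]]$b[] <- 0
  net$layers[[2]]$W[] <- 0
  net$layers[[2]]$b[] <- 0.5
  X <- matrix(c(-1, 0, 1), ncol = 1)
  expect_identical(predict(net, X), c(1L, 1L, 1L))  # output 0.5 >= 0.5
  net$layers[[2]]$b[] <- 0.49
  expect_identical(predict(net, X), c(0L, 0L, 0L))
})

test_that("parameter encoding round-trips and serializes", {
  net <- random_network(7)
  theta <- encode_network(net)
  expect_length(theta, n_network_params(net$sizes))
  back <- decode_network(theta, net$sizes, net$threshold)
  expect_equal(back$layers, net$layers)
  expect_error(decode_network(theta[-1], net$sizes), "length")

  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  loaded <- read_network(path)
  expect_equal(loaded$layers, net$layers, tolerance = 1e-12)
})
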