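# Dense multilayer network with Gaussian hidden activations and a linear
# output unit, trained online by backpropagation. The Gaussian unit
# responds maximally when its weighted input is zero, giving radial-
# basis-like hidden responses on projections of the input.

#' Gaussian activation
#' @param x Numeric input.
#' @return `exp(-x^2)`, in (0, 1].
#' @export
gaussian <- function(x) exp(-x^2)

# derivative of the Gaussian activation at pre-activation u
gaussian_grad <- function(u) -2 * u * exp(-u^2)

#' Weighted sum of inputs
#' @param f Input values.
#' @param w Weights, same length as `f`.
#' @return `sum(f * w)`.
#' @export
weighted_sum <- function(f, w) {
  if (length(f) != length(w)) stop("inputs and weights differ in length",
                                   call. = FALSE)
  sum(f * w)
}

#' Network configuration
#'
#' @param layer_sizes Integer vector: input width, hidden widths, then 1
#'   output unit. At least one hidden layer.
#' @param alpha Learning-rate (momentum) coefficient of the weight
#'   update, > 0.
#' @param epochs Training epochs.
#' @param init_scale Half-range of the uniform weight initialization.
#' @param threshold Decision cutoff on the linear output (label 1 when
#'   the output is >= threshold).
#' @param seed Integer seed for initialization and epoch shuffling.
#' @return A `network_config` list.
#' @export
network_config <- function(layer_sizes, alpha = 0.05, epochs = 100L,
                           init_scale = 0.5, threshold = 0.5, seed = 1L) {
  stopifnot(length(layer_sizes) >= 3, alpha > 0, epochs >= 0,
            init_scale > 0, utils::tail(layer_sizes, 1) == 1)
  structure(list(layer_sizes = as.integer(layer_sizes), alpha = alpha,
                 epochs = as.integer(epochs), init_scale = init_scale,
                 threshold = threshold, seed = seed),
            class = "network_config")
}

#' Initialize a network with seeded uniform random weights
#'
#' Weights and biases are drawn uniformly on
#' `[-init_scale, init_scale]`.
#'
#' @param cfg A [network_config()].
#' @return An `mldcnn` network: a list of layers with `W` (in x out) and
#'   `b` (out) entries; all layers but the last use the Gaussian
#'   activation, the output unit is linear.
#' @export
init_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  sizes <- cfg$layer_sizes
  layers <- with_seed(cfg$seed, lapply(seq_len(length(sizes) - 1L),
    function(l) {
      list(W = matrix(stats::runif(sizes[l] * sizes[l + 1L],
                                   -cfg$init_scale, cfg$init_scale),
                      nrow = sizes[l]),
           b = stats::runif(sizes[l + 1L], -cfg$init_scale, cfg$init_scale))
    }))
  structure(list(layers = layers, sizes = sizes, threshold = cfg$threshold),
            class = "mldcnn")
}

#' Forward pass for one input row, with trace
#'
#' Hidden layers compute `C = gaussian(M)` with `M` the bias-plus-
#' weighted-sum of the previous layer's outputs; the output unit is
#' linear. The trace records pre-activations and activations per layer
#' for use by backpropagation.
#'
#' @param net An `mldcnn` network.
#' @param x Numeric input row of length `net$sizes[1]`.
#' @return List with `output` (the scalar linear output) and `trace`
#'   (`pre` and `act` per layer; `act[[1]]` is the input).
#' @export
forward <- function(net, x) {
  stopifnot(inherits(net, "mldcnn"))
  if (length(x) != net$sizes[1]) stop("input width mismatch", call. = FALSE)
  L <- length(net$layers)
  act <- vector("list", L + 1L)
  pre <- vector("list", L)
  act[[1]] <- as.numeric(x)
  for (l in seq_len(L)) {
    pre[[l]] <- drop(act[[l]] %*% net$layers[[l]]$W) + net$layers[[l]]$b
    act[[l + 1L]] <- if (l < L) gaussian(pre[[l]]) else pre[[l]]
  }
  list(output = unname(act[[L + 1L]]), trace = list(pre = pre, act = act))
}

# Vectorized forward over a design matrix; returns the n-vector of
# linear outputs.
network_raw <- function(net, X) {
  A <- X
  L <- length(net$layers)
  for (l in seq_len(L)) {
    M <- sweep(A %*% net$layers[[l]]$W, 2L, net$layers[[l]]$b, "+")
    A <- if (l < L) gaussian(M) else M
  }
  drop(A)
}

#' Output error signal
#' @param d Target value.
#' @param r Network output.
#' @return `d - r`.
#' @export
output_error <- function(d, r) d - r

#' Backpropagated error signal of a unit
#'
#' Multiplies the incoming error by the unit's activation derivative
#' evaluated at its pre-activation: identically 1 for the linear output
#' unit, `-2u * exp(-u^2)` for a Gaussian unit.
#'
#' @param e Incoming error.
#' @param u Pre-activation of the unit.
#' @param unit `"linear"` or `"gaussian"`.
#' @return The propagated signal.
#' @export
error_signal <- function(e, u, unit = c("linear", "gaussian")) {
  unit <- match.arg(unit)
  if (unit == "linear") e else e * gaussian_grad(u)
}

#' Weight adjustment of the delta rule
#' @param alpha Learning-rate coefficient.
#' @param k Propagated error signal of the downstream unit.
#' @param f Upstream activation feeding the weight.
#' @return The additive weight delta `alpha * k * f`.
#' @export
weight_delta <- function(alpha, k, f) alpha * k * f

# one online backprop update for sample (x, d); returns the updated net
backprop_step <- function(net, x, d, alpha) {
  fw <- forward(net, x)
  L <- length(net$layers)
  deltas <- vector("list", L)
  deltas[[L]] <- output_error(d, fw$output)  # linear output: f' = 1
  if (L > 1L) {
    for (l in (L - 1L):1L) {
      back <- drop(net$layers[[l + 1L]]$W %*% deltas[[l + 1L]])
      deltas[[l]] <- back * gaussian_grad(fw$trace$pre[[l]])
    }
  }
  for (l in seq_len(L)) {
    net$layers[[l]]$W <- net$layers[[l]]$W +
      outer(fw$trace$act[[l]], deltas[[l]], function(f, k)
        weight_delta(alpha, k, f))
    net$layers[[l]]$b <- net$layers[[l]]$b + alpha * deltas[[l]]
  }
  net
}

#' Train a network by online backpropagation
#'
#' Samples are presented one at a time in a freshly shuffled order each
#' epoch; each presentation applies the delta-rule update with
#' coefficient `cfg$alpha` to every layer.
#'
#' @param net An `mldcnn` network (e.g. from [init_network()]).
#' @param X Numeric design matrix.
#' @param y 0/1 labels.
#' @param cfg A [network_config()].
#' @return List with `net` (trained network) and `loss` (epoch-wise mean
#'   squared error after each epoch).
#' @export
train_backprop <- function(net, X, y, cfg) {
  stopifnot(inherits(net, "mldcnn"), nrow(X) == length(y),
            all(y %in% 0:1))
  loss <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      for (i in sample.int(nrow(X))) {
        net <- backprop_step(net, X[i, ], y[i], cfg$alpha)
      }
      loss[epoch] <- mean((y - network_raw(net, X))^2)
      if (!is.finite(loss[epoch])) {
        stop("training diverged at epoch ", epoch, call. = FALSE)
      }
    }
  })
  list(net = net, loss = loss)
}

#' Predict binary labels
#' @param object An `mldcnn` network.
#' @param X Numeric design matrix.
#' @param threshold Decision cutoff; defaults to the network's own.
#' @param ... Unused.
#' @return Integer 0/1 labels (1 when the output is >= threshold).
#' @export
predict.mldcnn <- function(object, X, threshold = object$threshold, ...) {
  as.integer(network_raw(object, X) >= threshold)
}

#' Flatten network parameters to a vector
#'
#' Layer-major order, weights (column-major) then biases per layer; the
#' inverse of [decode_network()].
#'
#' @param net An `mldcnn` network.
#' @return Numeric parameter vector.
#' @export
encode_network <- function(net) {
  unlist(lapply(net$layers, function(l) c(as.vector(l$W), l$b)),
         use.names = FALSE)
}

#' Rebuild a network from a flat parameter vector
#' @param theta Numeric vector of length [n_network_params()].
#' @param sizes Layer sizes (input, hidden..., 1).
#' @param threshold Decision cutoff stored on the network.
#' @return An `mldcnn` network.
#' @export
decode_network <- function(theta, sizes, threshold = 0.5) {
  layers <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (l in seq_along(layers)) {
    nw <- sizes[l] * sizes[l + 1L]
    layers[[l]] <- list(
      W = matrix(theta[pos + seq_len(nw)], nrow = sizes[l]),
      b = theta[pos + nw + seq_len(sizes[l + 1L])])
    pos <- pos + nw + sizes[l + 1L]
  }
  if (pos != length(theta)) stop("parameter vector length mismatch",
                                 call. = FALSE)
  structure(list(layers = layers, sizes = as.integer(sizes),
                 threshold = threshold), class = "mldcnn")
}

#' Number of parameters of an architecture
#' @param sizes Layer sizes.
#' @return Total weight + bias count.
#' @export
n_network_params <- function(sizes) {
  sum(vapply(seq_len(length(sizes) - 1L), function(l)
    sizes[l] * sizes[l + 1L] + sizes[l + 1L], numeric(1)))
}

#' Serialize a network to JSON
#' @param net An `mldcnn` network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  jsonlite::write_json(list(sizes = net$sizes, threshold = net$threshold,
                            theta = encode_network(net)),
                       path, digits = NA)
  invisible(path)
}

#' Read a network serialized by [write_network()]
#' @param path JSON path.
#' @return An `mldcnn` network.
#' @export
read_network <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  decode_network(raw$theta, raw$sizes, raw$threshold)
}
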