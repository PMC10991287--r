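# Shared fixtures and independent oracles, built in code at test time.

uci_fixture_lines <- function() {
  c("63,1,1,145,233,1,2,150,0,2.3,3,0,6,0",
    "67,1,4,160,286,0,2,108,1,1.5,2,3,3,2",
    "41,0,2,130,204,0,2,172,0,1.4,1,0,3,1")
}

write_uci_fixture <- function(lines = uci_fixture_lines()) {
  path <- withr::local_tempfile(fileext = ".data",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# two well-separated Gaussian blobs for classifier checks
make_blobs <- function(n = 100, sep = 4, sd = 1, seed = 1) {
  hdpm:::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    X <- cbind(x1 = rnorm(n, ifelse(y == 1, sep / 2, -sep / 2), sd),
               x2 = rnorm(n, ifelse(y == 1, sep / 2, -sep / 2), sd))
    list(X = X, y = y)
  })
}

# Brute-force per-unit forward pass: nested loops over layers and units,
# independent of the matrix implementation.
forward_oracle <- function(net, x) {
  a <- as.numeric(x)
  L <- length(net$layers)
  for (l in seq_len(L)) {
    W <- net$layers[[l]]$W
    b <- net$layers[[l]]$b
    out <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) {
      s <- b[j]
      for (i in seq_len(nrow(W))) s <- s + a[i] * W[i, j]
      out[j] <- if (l < L) exp(-s^2) else s
    }
    a <- out
  }
  a
}

random_network <- function(seed) {
  hdpm:::with_seed(seed, {
    n_hidden <- sample(1:2, 1)
    sizes <- c(sample(2:6, 1), sample(2:8, n_hidden, replace = TRUE), 1L)
  })
  init_network(network_config(sizes, seed = seed))
}
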