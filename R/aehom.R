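# Adaptive elephant-herd optimization: a clan-structured metaheuristic.
# Clan members drift toward their matriarch (clan best), matriarchs move
# to a scaled clan center, the worst members of each clan are scattered
# to fresh random positions, and clan-best pairs exchange gene segments
# by two-point crossover, with per-gene mutation. Minimization
# convention: lower fitness is better, and the best position ever seen
# is archived (elitism).

#' Herd configuration
#'
#' @param dims Search-space dimensionality L.
#' @param lower,upper Per-dimension bounds (recycled to length `dims`).
#' @param n_clans Number of clans.
#' @param clan_size Elephants per clan.
#' @param c Matriarch-influence scale in \[0, 1\] of the clan update.
#' @param l Center-influence scale in \[0, 1\] of the matriarch update.
#' @param n_worst Worst elephants per clan re-scattered each generation
#'   (< clan_size).
#' @param generations Number of generations.
#' @param mutation_rate Per-gene mutation probability.
#' @param seed Integer seed for all herd randomness.
#' @return A `herd_config` list.
#' @export
herd_config <- function(dims, lower = -1, upper = 1, n_clans = 3L,
                        clan_size = 10L, c = 0.5, l = 0.1, n_worst = 2L,
                        generations = 100L, mutation_rate = 0.05,
                        seed = 1L) {
  lower <- rep_len(lower, dims)
  upper <- rep_len(upper, dims)
  stopifnot(dims >= 1, all(lower < upper), n_clans >= 1, clan_size >= 2,
            c >= 0, c <= 1, l >= 0, l <= 1, n_worst >= 0,
            n_worst < clan_size, generations >= 0,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(dims = as.integer(dims), lower = lower, upper = upper,
                 n_clans = as.integer(n_clans),
                 clan_size = as.integer(clan_size), c = c, l = l,
                 n_worst = as.integer(n_worst),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate, seed = seed),
            class = "herd_config")
}

clip_bounds <- function(p, lower, upper) pmin(pmax(p, lower), upper)

#' Clan-member position update
#'
#' Moves a member toward its clan best:
#' `p + c * (clan_best - p) * r_d`, clipped to the bounds.
#'
#' @param p Current position.
#' @param clan_best Matriarch (clan-best) position, same length.
#' @param c Influence scale in \[0, 1\].
#' @param r_d Random draw(s) in \[0, 1\] (scalar or per-dimension).
#' @param lower,upper Bounds.
#' @return The updated, clipped position.
#' @export
clan_update <- function(p, clan_best, c, r_d, lower = -Inf, upper = Inf) {
  if (length(p) != length(clan_best)) stop("dimension mismatch",
                                           call. = FALSE)
  stopifnot(all(r_d >= 0), all(r_d <= 1))
  clip_bounds(p + c * (clan_best - p) * r_d, lower, upper)
}

#' Matriarch position update
#'
#' The clan center is the per-dimension mean of the clan's positions;
#' the matriarch is moved to `l * center`, clipped to the bounds.
#'
#' @param clan_positions Matrix of clan positions (rows = elephants).
#' @param l Center-influence scale in \[0, 1\].
#' @param lower,upper Bounds.
#' @return The new matriarch position.
#' @export
matriarch_update <- function(clan_positions, l, lower = -Inf, upper = Inf) {
  if (!nrow(clan_positions)) stop("empty clan", call. = FALSE)
  clip_bounds(l * colMeans(clan_positions), lower, upper)
}

#' Scatter the worst members of a clan
#'
#' The `n_worst` highest-fitness (worst) elephants are replaced by fresh
#' uniform positions `lower + (upper - lower) * k`, `k ~ Uniform(0,1)`
#' per dimension.
#'
#' @param clan_positions Matrix of clan positions.
#' @param fitness Fitness of each row (lower is better).
#' @param n_worst Number to replace (< clan size).
#' @param lower,upper Bounds.
#' @param seed Optional integer seed.
#' @return The clan matrix with replacements.
#' @export
separate_worst <- function(clan_positions, fitness, n_worst, lower, upper,
                           seed = NULL) {
  if (n_worst >= nrow(clan_positions)) {
    stop("cannot scatter the whole clan", call. = FALSE)
  }
  if (n_worst == 0L) return(clan_positions)
  worst <- order(fitness, decreasing = TRUE)[seq_len(n_worst)]
  L <- ncol(clan_positions)
  with_seed(seed, {
    for (i in worst) {
      clan_positions[i, ] <- lower + (upper - lower) * stats::runif(L)
    }
    clan_positions
  })
}

#' Two-point crossover of two positions
#'
#' Cut points are fixed by the dimensionality: `x1 = floor(L/3)` and
#' `x2 = x1 + floor(L/2)`; the gene segment in \[x1, x2) (0-based) is
#' exchanged between the parents.
#'
#' @param p1,p2 Parent positions of length `L >= 6`.
#' @return List of the two children.
#' @export
crossover_positions <- function(p1, p2) {
  L <- length(p1)
  if (length(p2) != L) stop("dimension mismatch", call. = FALSE)
  if (L < 6L) stop("two-point crossover needs at least 6 genes",
                   call. = FALSE)
  x1 <- L %/% 3L
  x2 <- x1 + L %/% 2L
  seg <- (x1 + 1L):x2
  c1 <- p1; c2 <- p2
  c1[seg] <- p2[seg]
  c2[seg] <- p1[seg]
  list(c1, c2)
}

#' Per-gene mutation of a position
#'
#' Each gene is independently replaced, with probability `rate`, by a
#' fresh uniform draw within its bounds.
#'
#' @param p Position vector.
#' @param rate Per-gene probability in \[0, 1\].
#' @param lower,upper Bounds.
#' @param seed Optional integer seed.
#' @return The mutated position.
#' @export
mutate_position <- function(p, rate, lower, upper, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, {
    hit <- stats::runif(length(p)) < rate
    if (any(hit)) {
      lo <- rep_len(lower, length(p)); up <- rep_len(upper, length(p))
      p[hit] <- lo[hit] + (up[hit] - lo[hit]) * stats::runif(sum(hit))
    }
    p
  })
}

new_herd <- function(cfg) {
  n <- cfg$n_clans * cfg$clan_size
  P <- matrix(stats::runif(n * cfg$dims), nrow = n)
  P <- sweep(sweep(P, 2L, cfg$upper - cfg$lower, "*"), 2L, cfg$lower, "+")
  list(P = P, clan = rep(seq_len(cfg$n_clans), each = cfg$clan_size),
       best = NULL, best_fit = Inf, history = numeric(0))
}

#' Run the elephant-herd optimizer
#'
#' Per generation: clan updates toward each matriarch, matriarch moves to
#' the scaled clan center, worst-member scattering, two-point crossover
#' between the bests of randomly paired clans (skipped when `dims < 6`),
#' and per-gene mutation. The best-ever position is archived, so the
#' history never increases.
#'
#' @param fitness_fn Function from a position vector to a finite scalar;
#'   lower is better.
#' @param cfg A [herd_config()].
#' @param herd Optional warm-start herd state returned by a previous
#'   call (used to interleave with other training).
#' @return List with `par` (best position), `value` (best fitness),
#'   `history` (best-ever fitness per generation) and `herd` (final
#'   state for warm-starting).
#' @export
aehom_optimize <- function(fitness_fn, cfg, herd = NULL) {
  stopifnot(inherits(cfg, "herd_config"))
  eval_fit <- function(P) {
    f <- apply(P, 1L, fitness_fn)
    if (any(!is.finite(f))) stop("non-finite fitness encountered",
                                 call. = FALSE)
    f
  }
  with_seed(cfg$seed, {
    if (is.null(herd)) herd <- new_herd(cfg)
    P <- herd$P
    clan_id <- herd$clan
    fit <- eval_fit(P)
    if (min(fit) < herd$best_fit) {
      herd$best_fit <- min(fit)
      herd$best <- P[which.min(fit), ]
    }
    for (gen in seq_len(cfg$generations)) {
      # clan updates toward each matriarch
      for (cl in seq_len(cfg$n_clans)) {
        idx <- which(clan_id == cl)
        best_i <- idx[which.min(fit[idx])]
        for (i in setdiff(idx, best_i)) {
          P[i, ] <- clan_update(P[i, ], P[best_i, ], cfg$c,
                                stats::runif(cfg$dims),
                                cfg$lower, cfg$upper)
        }
        P[best_i, ] <- matriarch_update(P[idx, , drop = FALSE], cfg$l,
                                        cfg$lower, cfg$upper)
        fit[idx] <- eval_fit(P[idx, , drop = FALSE])
        P[idx, ] <- separate_worst(P[idx, , drop = FALSE], fit[idx],
                                   cfg$n_worst, cfg$lower, cfg$upper)
      }
      # two-point crossover between bests of randomly paired clans
      if (cfg$dims >= 6L && cfg$n_clans >= 2L) {
        pairing <- sample(seq_len(cfg$n_clans))
        for (j in seq_len(length(pairing) %/% 2L)) {
          ia <- which(clan_id == pairing[2 * j - 1])
          ib <- which(clan_id == pairing[2 * j])
          a <- ia[which.min(fit[ia])]
          b <- ib[which.min(fit[ib])]
          kids <- crossover_positions(P[a, ], P[b, ])
          P[a, ] <- kids[[1]]
          P[b, ] <- kids[[2]]
        }
      }
      # mutation
      for (i in seq_len(nrow(P))) {
        P[i, ] <- mutate_position(P[i, ], cfg$mutation_rate,
                                  cfg$lower, cfg$upper)
      }
      fit <- eval_fit(P)
      if (min(fit) < herd$best_fit) {
        herd$best_fit <- min(fit)
        herd$best <- P[which.min(fit), ]
      }
      herd$history <- c(herd$history, herd$best_fit)
    }
    herd$P <- P
    list(par = herd$best, value = herd$best_fit, history = herd$history,
         herd = herd)
  })
}

#' Train a network with AEHOM-optimized weights plus backprop refinement
#'
#' Herd positions decode to flattened network parameter vectors
#' (layer-major, weights then biases per layer); the fitness is the
#' training-set mean squared error of the decoded network. The schedule
#' interleaves blocks of AEHOM generations with online backprop epochs
#' applied to the incumbent best network (whose refined parameters
#' re-enter the herd, clipped to bounds, replacing the worst elephant).
#' After the herd phase the best network receives `net_cfg$epochs`
#' backprop epochs. With `herd_cfg$generations = 0` the procedure
#' reduces to pure backprop from the random initialization.
#'
#' @param net_cfg A [network_config()].
#' @param X Numeric design matrix.
#' @param y 0/1 labels.
#' @param herd_cfg A [herd_config()] with `dims` equal to the network's
#'   parameter count; `NULL` builds a default herd on \[-1, 1\] bounds.
#' @param block AEHOM generations between backprop interleaves.
#' @param refine_epochs Backprop epochs applied at each interleave.
#' @return List with `net` (trained network), `history` (herd best-ever
#'   MSE per generation) and `loss` (final backprop loss history).
#' @export
train_network_aehom <- function(net_cfg, X, y, herd_cfg = NULL,
                                block = 5L, refine_epochs = 1L) {
  stopifnot(inherits(net_cfg, "network_config"))
  L <- n_network_params(net_cfg$layer_sizes)
  if (is.null(herd_cfg)) {
    herd_cfg <- herd_config(dims = L, lower = -1, upper = 1,
                            seed = net_cfg$seed)
  }
  if (herd_cfg$dims != L) {
    stop(sprintf("herd dimension %d != network parameter count %d",
                 herd_cfg$dims, L), call. = FALSE)
  }
  fitness_fn <- function(theta) {
    mean((y - network_raw(decode_network(theta, net_cfg$layer_sizes,
                                         net_cfg$threshold), X))^2)
  }
  refine_cfg <- network_config(net_cfg$layer_sizes, alpha = net_cfg$alpha,
                               epochs = refine_epochs,
                               init_scale = net_cfg$init_scale,
                               threshold = net_cfg$threshold,
                               seed = net_cfg$seed)
  history <- numeric(0)
  if (herd_cfg$generations > 0L) {
    state <- NULL
    remaining <- herd_cfg$generations
    chunk_i <- 0L
    while (remaining > 0L) {
      chunk_i <- chunk_i + 1L
      g <- min(block, remaining)
      cfg_chunk <- herd_cfg
      cfg_chunk$generations <- as.integer(g)
      cfg_chunk$seed <- derive_seed(herd_cfg$seed, 100L + chunk_i)
      res <- aehom_optimize(fitness_fn, cfg_chunk, herd = state)
      state <- res$herd
      remaining <- remaining - g
      if (remaining > 0L && refine_epochs > 0L) {
        net <- decode_network(state$best, net_cfg$layer_sizes,
                              net_cfg$threshold)
        net <- train_backprop(net, X, y, refine_cfg)$net
        theta <- clip_bounds(encode_network(net), herd_cfg$lower,
                             herd_cfg$upper)
        f <- fitness_fn(theta)
        worst <- which.max(apply(state$P, 1L, fitness_fn))
        state$P[worst, ] <- theta
        if (f < state$best_fit) {
          state$best_fit <- f
          state$best <- theta
        }
      }
    }
    history <- state$history
    net <- decode_network(state$best, net_cfg$layer_sizes,
                          net_cfg$threshold)
  } else {
    net <- init_network(net_cfg)
  }
  final_cfg <- net_cfg
  trained <- if (net_cfg$epochs > 0L) train_backprop(net, X, y, final_cfg)
             else list(net = net, loss = numeric(0))
  list(net = trained$net, history = history, loss = trained$loss)
}
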