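# Hybrid feature selection: a genetic algorithm searches feature bitmasks
# globally, then recursive feature elimination refines the winning subset.

#' Genetic-algorithm configuration for feature selection
#'
#' Defaults follow the published search protocol: 18 generations of 80
#' genomes, 40 elites carried forward plus 40 fresh random genomes, a 5%
#' crossover rate and a 0.05 per-bit mutation rate.
#'
#' @param generations Number of generations.
#' @param population Genomes per generation.
#' @param elites Lowest-MSE genomes carried into the mating pool.
#' @param randoms Fresh random genomes injected each generation.
#' @param crossover_rate Probability a mating-pool pair undergoes
#'   single-point crossover.
#' @param mutation_rate Per-bit flip probability.
#' @param cv_folds Folds for the cross-validated MSE fitness.
#' @param lambda Ridge penalty of the base learner.
#' @param seed Integer seed controlling folds and all GA randomness.
#' @return A `ga_config` list.
#' @export
ga_config <- function(generations = 18, population = 80, elites = 40,
                      randoms = 40, crossover_rate = 0.05,
                      mutation_rate = 0.05, cv_folds = 3, lambda = 1e-3,
                      seed = 1L) {
  stopifnot(generations >= 0, population >= 1,
            elites >= 1, randoms >= 0, elites + randoms <= population,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, cv_folds >= 2)
  structure(as.list(environment()), class = "ga_config")
}

#' Recursive-feature-elimination configuration
#' @param n_keep Target number of features to retain.
#' @param step Features removed per elimination round.
#' @param lambda Ridge penalty of the ranking learner.
#' @return An `rfe_config` list.
#' @export
rfe_config <- function(n_keep, step = 1L, lambda = 1e-3) {
  stopifnot(n_keep >= 1, step >= 1)
  structure(list(n_keep = as.integer(n_keep), step = as.integer(step),
                 lambda = lambda), class = "rfe_config")
}

#' Cross-validated MSE fitness of a feature mask
#'
#' Fits the ridge base learner on the masked columns under seeded
#' `cv_folds`-fold cross-validation and returns the held-out mean squared
#' error against the 0/1 labels (lower is better). The all-zero mask is
#' assigned `Inf` rather than raising.
#'
#' @param mask Logical vector over the columns of `X`.
#' @param X Numeric design matrix.
#' @param y 0/1 labels.
#' @param seed Integer seed fixing the fold assignment.
#' @param cv_folds Number of folds.
#' @param lambda Ridge penalty.
#' @return The CV mean squared error.
#' @export
genome_fitness <- function(mask, X, y, seed = 1L, cv_folds = 3,
                           lambda = 1e-3) {
  stopifnot(length(mask) == ncol(X), length(y) == nrow(X))
  mask <- as.logical(mask)
  if (!any(mask)) return(Inf)
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  Xm <- X[, mask, drop = FALSE]
  sq_err <- numeric(n)
  for (f in seq_len(cv_folds)) {
    test <- folds == f
    beta <- ridge_coef(Xm[!test, , drop = FALSE], y[!test], lambda)
    sq_err[test] <- (y[test] - ridge_predict(beta, Xm[test, , drop = FALSE]))^2
  }
  mean(sq_err)
}

#' Pick the n best genomes of a population
#'
#' Genomes are lists with `mask` and `fitness`; the `n` lowest-fitness
#' genomes are returned, ties broken by earlier position.
#'
#' @param pop List of genomes.
#' @param n Number to select (at most `length(pop)`).
#' @return List of the selected genomes, best first.
#' @export
select_elites <- function(pop, n) {
  if (n > length(pop)) stop("cannot select more elites than genomes",
                            call. = FALSE)
  fit <- vapply(pop, `[[`, numeric(1), "fitness")
  pop[order(fit, seq_along(fit))[seq_len(n)]]
}

#' Single-point crossover of two feature masks
#'
#' With probability `rate` the parents exchange tails at a uniformly
#' drawn cut point; otherwise they are returned unchanged.
#'
#' @param a,b Logical masks of equal length (>= 2).
#' @param rate Crossover probability in \[0, 1\].
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return List of the two offspring masks.
#' @export
crossover_genomes <- function(a, b, rate = 0.05, seed = NULL) {
  if (length(a) != length(b)) stop("mask lengths differ", call. = FALSE)
  with_seed(seed, {
    if (stats::runif(1) < rate && length(a) >= 2L) {
      cut <- sample.int(length(a) - 1L, 1L)
      head_idx <- seq_len(cut)
      list(c(a[head_idx], b[-head_idx]), c(b[head_idx], a[-head_idx]))
    } else {
      list(a, b)
    }
  })
}

#' Per-bit mutation of a feature mask
#' @param mask Logical mask.
#' @param rate Per-bit flip probability.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return The mutated mask.
#' @export
mutate_genome <- function(mask, rate = 0.05, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, xor(mask, stats::runif(length(mask)) < rate))
}

random_mask <- function(p) {
  mask <- stats::runif(p) < 0.5
  if (!any(mask)) mask[sample.int(p, 1L)] <- TRUE
  mask
}

#' Genetic-algorithm feature search
#'
#' Runs an elitist GA over feature bitmasks with cross-validated ridge
#' MSE as the (minimized) fitness. Each generation keeps the
#' `cfg$elites` best genomes as the mating pool, applies single-point
#' crossover and per-bit mutation to that pool, and injects
#' `cfg$randoms` fresh random genomes. The best genome ever seen is
#' archived, so the reported history never increases.
#'
#' @param X Numeric design matrix (p >= 2 columns).
#' @param y 0/1 labels.
#' @param cfg A [ga_config()].
#' @return List with `mask` (best-ever mask), `fitness`, `features`
#'   (selected column names) and `history` (best-ever fitness after the
#'   initial population and each generation).
#' @export
ga_select <- function(X, y, cfg = ga_config()) {
  stopifnot(inherits(cfg, "ga_config"), ncol(X) >= 2,
            nrow(X) >= 2 * cfg$cv_folds)
  p <- ncol(X)
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (is.null(cache[[key]])) {
      cache[[key]] <- genome_fitness(mask, X, y, seed = cfg$seed,
                                     cv_folds = cfg$cv_folds,
                                     lambda = cfg$lambda)
    }
    cache[[key]]
  }
  with_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$population), function(i) {
      mask <- random_mask(p)
      list(mask = mask, fitness = fitness_of(mask))
    })
    best <- select_elites(pop, 1L)[[1]]
    history <- best$fitness
    for (gen in seq_len(cfg$generations)) {
      pool <- select_elites(pop, cfg$elites)
      # crossover on consecutive mating-pool pairs, then mutation
      for (i in seq_len(length(pool) %/% 2L)) {
        kids <- crossover_genomes(pool[[2 * i - 1]]$mask, pool[[2 * i]]$mask,
                                  rate = cfg$crossover_rate)
        pool[[2 * i - 1]]$mask <- kids[[1]]
        pool[[2 * i]]$mask <- kids[[2]]
      }
      pool <- lapply(pool, function(g) {
        g$mask <- mutate_genome(g$mask, cfg$mutation_rate)
        g$fitness <- fitness_of(g$mask)
        g
      })
      n_fresh <- cfg$population - length(pool)
      fresh <- lapply(seq_len(n_fresh), function(i) {
        mask <- random_mask(p)
        list(mask = mask, fitness = fitness_of(mask))
      })
      pop <- c(pool, fresh)
      gen_best <- select_elites(pop, 1L)[[1]]
      if (gen_best$fitness < best$fitness) best <- gen_best
      history <- c(history, best$fitness)
    }
    list(mask = best$mask, fitness = best$fitness,
         features = colnames(X)[best$mask], history = history)
  })
}

#' Recursive feature elimination
#'
#' Repeatedly fits the ridge ranking learner on internally standardized
#' columns, scores each feature by its absolute coefficient, drops the
#' lowest-ranked `step` features and refits, until `n_keep` remain.
#'
#' @param X Numeric design matrix with named columns.
#' @param y 0/1 labels.
#' @param cfg An [rfe_config()] (or `n_keep` given directly).
#' @return Character vector of kept feature names, in original column
#'   order, with final importances as the `importance` attribute.
#' @export
rfe_select <- function(X, y, cfg) {
  if (is.numeric(cfg)) cfg <- rfe_config(cfg)
  stopifnot(inherits(cfg, "rfe_config"))
  if (cfg$n_keep > ncol(X)) {
    stop(sprintf("n_keep = %d exceeds the %d available features",
                 cfg$n_keep, ncol(X)), call. = FALSE)
  }
  current <- colnames(X)
  importance <- NULL
  repeat {
    Xc <- scale(X[, current, drop = FALSE])
    beta <- ridge_coef(Xc, y, cfg$lambda)
    importance <- abs(beta[-1L])
    names(importance) <- current
    if (length(current) <= cfg$n_keep) break
    n_drop <- min(cfg$step, length(current) - cfg$n_keep)
    drop_idx <- order(importance, seq_along(importance))[seq_len(n_drop)]
    current <- current[-drop_idx]
  }
  kept <- colnames(X)[colnames(X) %in% current]
  structure(kept, importance = importance[kept])
}

#' Hybrid GA + RFE feature selection
#'
#' Global search first: the GA proposes a feature subset; RFE then
#' refines it down to `rfe_cfg$n_keep` features. The result is always a
#' subset of the GA winner.
#'
#' @param X Numeric design matrix with named columns.
#' @param y 0/1 labels.
#' @param ga_cfg A [ga_config()].
#' @param rfe_cfg An [rfe_config()].
#' @param clamp When `TRUE`, an `n_keep` larger than the GA subset is
#'   clamped to the subset size instead of raising.
#' @return List with `features` (final kept names), `ga` (the
#'   [ga_select()] result) and `importance` of the survivors.
#' @export
hybrid_select <- function(X, y, ga_cfg = ga_config(), rfe_cfg,
                          clamp = FALSE) {
  ga <- ga_select(X, y, ga_cfg)
  if (rfe_cfg$n_keep > length(ga$features)) {
    if (!clamp) {
      stop(sprintf(
        "n_keep = %d exceeds the GA-selected subset of %d features",
        rfe_cfg$n_keep, length(ga$features)), call. = FALSE)
    }
    rfe_cfg$n_keep <- length(ga$features)
  }
  kept <- rfe_select(X[, ga$features, drop = FALSE], y, rfe_cfg)
  list(features = as.character(kept), ga = ga,
       importance = attr(kept, "importance"))
}
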