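# USCOM: under-sampling / clustering / over-sampling. The majority class
# is randomly under-sampled, the minority class is clustered so each
# subgroup contributes to every role, each group is split 8:1:1, and the
# merged training set is balanced by SMOTE. Validation and test sets
# contain original rows only.

#' USCOM configuration
#'
#' @param undersample_ratio Fraction of the majority class retained
#'   (default 2/3, the published imbalance ratio of the reference
#'   critical-care cohort; configurable because other cohorts differ).
#' @param k_range Candidate cluster counts for the minority class.
#' @param elbow_threshold Relative SSE improvement below which adding a
#'   cluster stops paying (default 0.10).
#' @param smote_k Neighbor count for SMOTE (clamped to minority size - 1).
#' @param split Train/validation/test ratios; must sum to 1.
#' @param seed Integer seed for all resampling randomness.
#' @return A `uscom_config` list.
#' @export
uscom_config <- function(undersample_ratio = 2 / 3, k_range = 1:6,
                         elbow_threshold = 0.10, smote_k = 5L,
                         split = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(undersample_ratio > 0, undersample_ratio <= 1,
            length(k_range) >= 1, !is.unsorted(k_range),
            elbow_threshold > 0, smote_k >= 1,
            length(split) == 3, abs(sum(split) - 1) < 1e-9)
  structure(as.list(environment()), class = "uscom_config")
}

#' Randomly under-sample the majority class
#' @param majority_ids Row indices of the majority class.
#' @param ratio Fraction to retain, in (0, 1].
#' @param seed Optional integer seed.
#' @return `round(ratio * n)` distinct ids, sampled without replacement.
#' @export
undersample_majority <- function(majority_ids, ratio = 2 / 3, seed = NULL) {
  if (!length(majority_ids)) stop("majority class is empty", call. = FALSE)
  stopifnot(ratio > 0, ratio <= 1)
  n_keep <- max(1L, round(ratio * length(majority_ids)))
  with_seed(seed, sample(majority_ids, n_keep))
}

#' K-means clustering with the total within-cluster squared error
#'
#' Lloyd's algorithm from seeded random initial centroids; the model
#' records the assignment and the summed squared Euclidean distance of
#' every sample to its centroid (SSE).
#'
#' @param X Numeric matrix (rows = samples).
#' @param K Number of clusters, 1 <= K <= nrow(X).
#' @param seed Optional integer seed for the initialization.
#' @return List with `K`, `centroids`, `assignment` and `sse`.
#' @export
kmeans_fit <- function(X, K, seed = NULL) {
  stopifnot(is.matrix(X))
  if (K < 1 || K > nrow(X)) {
    stop("K must lie in 1..n", call. = FALSE)
  }
  if (K == nrow(X)) {
    return(list(K = K, centroids = X, assignment = seq_len(nrow(X)),
                sse = 0))
  }
  fit <- NULL
  for (attempt in 1:10) {
    fit <- with_seed(if (is.null(seed)) NULL else seed + attempt - 1L,
      tryCatch(suppressWarnings(
        stats::kmeans(X, centers = K, iter.max = 300L, nstart = 5L,
                      algorithm = "Lloyd")),
        error = function(e) NULL))
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("k-means failed to produce K nonempty clusters",
                         call. = FALSE)
  list(K = K, centroids = fit$centers, assignment = fit$cluster,
       sse = fit$tot.withinss)
}

#' Choose the cluster count by the SSE elbow
#'
#' Fits k-means for each candidate K and returns the K after which the
#' SSE improvement, measured relative to the first candidate's SSE,
#' first drops below `elbow_threshold`; if the improvement never
#' flattens, the largest candidate is returned. A degenerate cloud
#' (zero SSE at the smallest K) yields the smallest candidate.
#'
#' @param X Numeric matrix.
#' @param k_range Increasing candidate cluster counts.
#' @param elbow_threshold Relative improvement cutoff.
#' @param seed Optional integer seed.
#' @return The chosen K.
#' @export
choose_k <- function(X, k_range = 1:6, elbow_threshold = 0.10, seed = NULL) {
  if (!length(k_range) || is.unsorted(k_range)) {
    stop("k_range must be a nonempty increasing vector", call. = FALSE)
  }
  k_range <- k_range[k_range <= nrow(X)]
  if (!length(k_range)) return(1L)
  if (length(k_range) == 1L) return(k_range)
  sse_at <- function(i) kmeans_fit(X, k_range[i],
                                   seed = derive_seed(seed %||% 0L, i))$sse
  sse1 <- sse_at(1L)
  if (sse1 <= 0) return(k_range[1])
  prev <- sse1
  for (i in 2:length(k_range)) {
    cur <- sse_at(i)
    if ((prev - cur) / sse1 < elbow_threshold) return(k_range[i - 1])
    prev <- cur
  }
  k_range[length(k_range)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split row ids 8:1:1 into train/validation/test
#'
#' After a seeded shuffle, the test and validation sets each get
#' `max(1, round(share * n))` rows and the training set the remainder.
#'
#' @param rows Vector of row ids (length >= 3).
#' @param seed Optional integer seed.
#' @param split Length-3 ratios summing to 1 (train, validation, test).
#' @return List with `train`, `validation`, `test` id vectors.
#' @export
split_8_1_1 <- function(rows, seed = NULL, split = c(0.8, 0.1, 0.1)) {
  n <- length(rows)
  if (n < 3L) stop("need at least 3 rows to split", call. = FALSE)
  shuffled <- with_seed(seed, sample(rows))
  n_test <- max(1L, round(split[3] * n))
  n_val <- max(1L, round(split[2] * n))
  list(train = shuffled[seq_len(n - n_val - n_test)],
       validation = shuffled[seq_len(n_val) + (n - n_val - n_test)],
       test = shuffled[seq_len(n_test) + (n - n_test)])
}

#' SMOTE: synthetic minority over-sampling
#'
#' Each synthetic row interpolates between a randomly chosen minority
#' seed point and one of its `k` nearest minority neighbors:
#' `seed + u * (neighbor - seed)` with `u ~ Uniform(0, 1)`. Neighbors
#' are found by Euclidean distance on internally standardized columns so
#' that large-scale attributes do not dominate; interpolation happens on
#' the original scales.
#'
#' @param minority Numeric matrix of minority rows (>= 2 rows).
#' @param n_new Number of synthetic rows to generate.
#' @param k Neighbor count (clamped to `nrow(minority) - 1`).
#' @param seed Optional integer seed.
#' @return An `n_new` x p matrix of synthetic rows.
#' @export
smote <- function(minority, n_new, k = 5L, seed = NULL) {
  stopifnot(is.matrix(minority), n_new >= 0, k >= 1)
  if (nrow(minority) < 2L) {
    stop("SMOTE needs at least 2 minority rows", call. = FALSE)
  }
  if (n_new == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = ncol(minority),
                  dimnames = list(NULL, colnames(minority))))
  }
  k <- min(k, nrow(minority) - 1L)
  sds <- apply(minority, 2L, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  Z <- sweep(sweep(minority, 2L, colMeans(minority), "-"), 2L, sds, "/")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  ord <- apply(D, 1L, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  with_seed(seed, {
    seeds_idx <- sample.int(nrow(minority), n_new, replace = TRUE)
    picks <- nn[cbind(seeds_idx, sample.int(k, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    out <- minority[seeds_idx, , drop = FALSE] +
      u * (minority[picks, , drop = FALSE] -
             minority[seeds_idx, , drop = FALSE])
    attr(out, "seed_idx") <- seeds_idx
    attr(out, "neighbor_idx") <- picks
    out
  })
}

#' Run the full USCOM resampling procedure
#'
#' (1) under-sample the majority class; (2) cluster the minority class
#' with the elbow-chosen K; (3) split the retained majority rows and each
#' minority cluster 8:1:1 and merge per role; (4) SMOTE the merged
#' training set until its two class counts are equal. Under-sampling can
#' flip which class is rarer in the merged training set, so step (4)
#' over-samples whichever class is smaller there. Clusters with fewer
#' than 3 rows go entirely to training. Synthetic rows appear only in
#' the training set.
#'
#' @param X Numeric design matrix.
#' @param y 0/1 labels (both classes present).
#' @param cfg A [uscom_config()].
#' @return A `split_bundle`: per-role lists with `X`, `y` and
#'   `provenance` (`"original"` or `"synthetic"`), plus a `meta` list
#'   (chosen K, counts, majority label).
#' @export
run_uscom <- function(X, y, cfg = uscom_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% 0:1),
            inherits(cfg, "uscom_config"))
  counts <- table(factor(y, levels = 0:1))
  if (any(counts == 0)) stop("both classes must be present", call. = FALSE)
  majority_label <- if (counts[["1"]] > counts[["0"]]) 1L else 0L
  minority_label <- 1L - majority_label
  maj_ids <- which(y == majority_label)
  min_ids <- which(y == minority_label)

  maj_kept <- undersample_majority(maj_ids, cfg$undersample_ratio,
                                   seed = derive_seed(cfg$seed, 1L))
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  K <- choose_k(Z[min_ids, , drop = FALSE], cfg$k_range,
                cfg$elbow_threshold, seed = derive_seed(cfg$seed, 2L))
  km <- kmeans_fit(Z[min_ids, , drop = FALSE], K,
                   seed = derive_seed(cfg$seed, 3L))

  groups <- c(list(maj_kept),
              lapply(seq_len(K), function(cl) min_ids[km$assignment == cl]))
  roles <- list(train = integer(0), validation = integer(0),
                test = integer(0))
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    if (!length(ids)) next
    if (length(ids) < 3L) {
      roles$train <- c(roles$train, ids)
    } else {
      sp <- split_8_1_1(ids, seed = derive_seed(cfg$seed, 10L + g),
                        split = cfg$split)
      roles$train <- c(roles$train, sp$train)
      roles$validation <- c(roles$validation, sp$validation)
      roles$test <- c(roles$test, sp$test)
    }
  }

  make_role <- function(ids) {
    list(X = X[ids, , drop = FALSE], y = y[ids],
         provenance = rep("original", length(ids)), row_ids = ids)
  }
  bundle <- lapply(roles, make_role)

  train_counts <- table(factor(bundle$train$y, levels = 0:1))
  rare_label <- if (train_counts[["1"]] < train_counts[["0"]]) 1L else 0L
  n_new <- abs(train_counts[["0"]] - train_counts[["1"]])
  if (n_new > 0L) {
    min_train <- bundle$train$X[bundle$train$y == rare_label, ,
                                drop = FALSE]
    if (nrow(min_train) < 2L) {
      stop("too few minority training rows for SMOTE", call. = FALSE)
    }
    synth <- smote(min_train, n_new, k = cfg$smote_k,
                   seed = derive_seed(cfg$seed, 4L))
    bundle$train$X <- rbind(bundle$train$X, synth)
    bundle$train$y <- c(bundle$train$y, rep(rare_label, n_new))
    bundle$train$provenance <- c(bundle$train$provenance,
                                 rep("synthetic", n_new))
    bundle$train$row_ids <- c(bundle$train$row_ids, rep(NA_integer_, n_new))
  }
  structure(c(bundle, list(meta = list(
    K = K, majority_label = majority_label,
    n_synthetic = n_new, undersampled_majority = length(maj_kept),
    train_counts = table(factor(bundle$train$y, levels = 0:1))
  ))), class = "split_bundle")
}

#' Write a split bundle to CSV files plus a JSON manifest
#'
#' @param bundle A `split_bundle` from [run_uscom()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_split_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "split_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (role in c("train", "validation", "test")) {
    df <- as.data.frame(bundle[[role]]$X)
    df$label <- bundle[[role]]$y
    df$provenance <- bundle[[role]]$provenance
    utils::write.csv(df, file.path(dir, paste0(role, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    counts = lapply(c(train = "train", validation = "validation",
                      test = "test"),
                    function(r) length(bundle[[r]]$y)),
    n_synthetic = bundle$meta$n_synthetic,
    K = bundle$meta$K
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
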