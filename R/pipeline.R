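# End-to-end orchestration: load or simulate records, preprocess, select
# features (GA + RFE), balance with USCOM, train the Gaussian-activation
# network with AEHOM + backprop, and report train/validation/test
# metrics. A single global seed derives every stage seed by a fixed
# counter scheme, so identical configurations reproduce identical runs.

#' Build a full pipeline configuration
#'
#' Every argument overrides a stage default; stage seeds are derived
#' from the single global `seed`.
#'
#' @param seed Global integer seed.
#' @param data_path Optional UCI-dialect input file; when `NULL` the
#'   synthetic generator supplies the cohort.
#' @param synthetic A [tabular_spec()] used when `data_path` is `NULL`.
#' @param cohort A [cohort_spec()] for imputation.
#' @param n_keep Features retained by the RFE refinement.
#' @param clamp_n_keep When `TRUE` (default) an `n_keep` exceeding the
#'   GA-selected subset is clamped to the subset size; when `FALSE`
#'   the fit raises a configuration error instead.
#' @param ga Named list of [ga_config()] overrides.
#' @param uscom Named list of [uscom_config()] overrides.
#' @param hidden Hidden-layer sizes of the network.
#' @param network Named list of [network_config()] overrides
#'   (`alpha`, `epochs`, `init_scale`, `threshold`).
#' @param aehom Named list of [herd_config()] overrides plus optional
#'   `block` and `refine_epochs` for the backprop interleave.
#' @return An `mlhdpm_config` nested list.
#' @export
mlhdpm_config <- function(seed = 1L, data_path = NULL,
                          synthetic = tabular_spec(seed = seed),
                          cohort = cohort_spec(), n_keep = 6L,
                          clamp_n_keep = TRUE,
                          ga = list(), uscom = list(), hidden = 6L,
                          network = list(), aehom = list()) {
  structure(list(seed = as.integer(seed), data_path = data_path,
                 synthetic = synthetic, cohort = cohort,
                 n_keep = as.integer(n_keep),
                 clamp_n_keep = isTRUE(clamp_n_keep),
                 ga = ga, uscom = uscom,
                 hidden = as.integer(hidden), network = network,
                 aehom = aehom),
            class = "mlhdpm_config")
}

merge_cfg <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

#' Fit the ML-HDPM model on a training set
#'
#' Standard-scales the predictors, runs hybrid GA + RFE selection,
#' balances the training data with USCOM, and trains the
#' Gaussian-activation network with AEHOM followed by backprop. All
#' resampling and training stay inside the rows given, so the function
#' is safe to call inside a cross-validation fold.
#'
#' @param X Numeric design matrix (named columns).
#' @param y 0/1 labels.
#' @param cfg An [mlhdpm_config()].
#' @param seed Seed for this fit; defaults to the config's global seed.
#' @return An `mlhdpm_model` list: `features`, `scaler`, `net`,
#'   `bundle` (the USCOM split), `selection` and `training` details.
#' @export
mlhdpm_fit <- function(X, y, cfg = mlhdpm_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "mlhdpm_config"))
  scaled <- standard_scale(X)

  ga_cfg <- do.call(ga_config, merge_cfg(list(seed = derive_seed(seed, 21L)),
                                         cfg$ga))
  sel <- tryCatch(
    hybrid_select(scaled$X, y, ga_cfg, rfe_config(cfg$n_keep),
                  clamp = cfg$clamp_n_keep),
    error = function(e) stop("feature_selection stage: ",
                             conditionMessage(e), call. = FALSE))

  us_cfg <- do.call(uscom_config,
                    merge_cfg(list(seed = derive_seed(seed, 22L)),
                              cfg$uscom))
  bundle <- run_uscom(X[, sel$features, drop = FALSE], y, us_cfg)

  train_scaler <- standard_scale(bundle$train$X)
  net_defaults <- list(layer_sizes = c(length(sel$features), cfg$hidden, 1L),
                       alpha = 0.05, epochs = 60L, init_scale = 0.5,
                       threshold = 0.5, seed = derive_seed(seed, 23L))
  net_cfg <- do.call(network_config, merge_cfg(net_defaults, cfg$network))

  aehom_over <- cfg$aehom
  block <- aehom_over$block %||% 5L
  refine_epochs <- aehom_over$refine_epochs %||% 1L
  aehom_over$block <- NULL
  aehom_over$refine_epochs <- NULL
  herd_defaults <- list(dims = n_network_params(net_cfg$layer_sizes),
                        lower = -1, upper = 1, n_clans = 3L,
                        clan_size = 10L, generations = 20L,
                        seed = derive_seed(seed, 24L))
  herd_cfg <- do.call(herd_config, merge_cfg(herd_defaults, aehom_over))

  trained <- train_network_aehom(net_cfg, train_scaler$X, bundle$train$y,
                                 herd_cfg, block = block,
                                 refine_epochs = refine_epochs)
  structure(list(features = sel$features, scaler = train_scaler$params,
                 net = trained$net, bundle = bundle, selection = sel,
                 training = list(herd_history = trained$history,
                                 loss = trained$loss),
                 seed = seed),
            class = "mlhdpm_model")
}

#' Predict disease labels with a fitted ML-HDPM model
#' @param object An `mlhdpm_model` from [mlhdpm_fit()].
#' @param X Design matrix containing the model's feature columns.
#' @param ... Unused.
#' @return Integer 0/1 labels.
#' @export
predict.mlhdpm_model <- function(object, X, ...) {
  Xs <- apply_scaler(X[, object$features, drop = FALSE], object$scaler)
  predict(object$net, Xs)
}

#' Run the full ML-HDPM pipeline
#'
#' Loads (or simulates) the cohort, imputes and deduplicates, fits the
#' model, and evaluates it on the USCOM training, validation and test
#' sets. The run report carries all six metrics per role, the selected
#' features, class counts, seeds and stage timings.
#'
#' @param cfg An [mlhdpm_config()].
#' @return An `mlhdpm_report` list.
#' @export
run_mlhdpm <- function(cfg = mlhdpm_config()) {
  stopifnot(inherits(cfg, "mlhdpm_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }

  if (!is.null(cfg$data_path)) {
    records <- read_uci_heart(cfg$data_path)
  } else {
    records <- gen_tabular(cfg$synthetic)$records
    if (is.null(records)) stop("synthetic schema must use p = 13",
                               call. = FALSE)
  }
  tick("load")

  records <- deduplicate(impute_missing(records, cfg$cohort))
  dat <- records_matrix(records)
  tick("preprocess")

  model <- mlhdpm_fit(dat$X, dat$y, cfg)
  tick("fit")

  metrics <- lapply(c(train = "train", validation = "validation",
                      test = "test"), function(role) {
    part <- model$bundle[[role]]
    Xs <- apply_scaler(part$X, model$scaler)
    m <- evaluate_predictions(part$y, predict(model$net, Xs))
    attributes(m) <- list(names = names(m))
    as.list(m)
  })
  tick("evaluate")

  structure(list(
    seed = cfg$seed,
    n_records = nrow(records),
    class_counts = as.list(table(factor(dat$y, levels = 0:1))),
    selected_features = model$features,
    uscom = list(K = model$bundle$meta$K,
                 n_synthetic = model$bundle$meta$n_synthetic,
                 train_counts = as.list(model$bundle$meta$train_counts)),
    metrics = metrics,
    timings = timings,
    model = model
  ), class = "mlhdpm_report")
}

#' Serialize a run report to JSON
#'
#' The model object stays out of the file; timings are included but are
#' the only non-reproducible entries.
#'
#' @param report An `mlhdpm_report`.
#' @param path Output path.
#' @param include_timings Set `FALSE` for byte-reproducible output.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path, include_timings = TRUE) {
  stopifnot(inherits(report, "mlhdpm_report"))
  out <- unclass(report)
  out$model <- NULL
  if (!include_timings) out$timings <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Cross-validate the full pipeline
#'
#' Stratified k-fold evaluation where each training fold is imputed,
#' selected, USCOM-balanced and trained independently (resampling never
#' touches the test fold).
#'
#' @param X Numeric design matrix.
#' @param y 0/1 labels.
#' @param cfg An [mlhdpm_config()].
#' @param k Number of folds.
#' @param seed Fold seed; defaults to the config's global seed.
#' @return As [kfold_evaluate()].
#' @export
mlhdpm_cv <- function(X, y, cfg = mlhdpm_config(), k = 10L,
                      seed = cfg$seed) {
  kfold_evaluate(function(Xtr, ytr, Xte, fold_seed) {
    model <- mlhdpm_fit(Xtr, ytr, cfg, seed = fold_seed)
    predict(model, Xte)
  }, X, y, k = k, seed = seed)
}
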