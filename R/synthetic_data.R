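# Seeded synthetic-data generators emulating the 14-attribute heart-
# disease schema (13 predictors, graded 0-4 outcome, 164:139-style class
# balance, `?` missingness) and RR-interval series, so that every
# pipeline stage is testable without external downloads.

# Marginal scales for the continuous attributes (means/sds chosen to
# resemble a typical adult cardiology cohort).
TABULAR_MARGINALS <- list(
  age = c(mean = 54, sd = 9), trestbps = c(mean = 131, sd = 17),
  chol = c(mean = 246, sd = 52), thalach = c(mean = 150, sd = 23),
  oldpeak = c(mean = 1.0, sd = 1.1)
)

#' Specification of a synthetic tabular cohort
#'
#' @param n Number of records.
#' @param p Number of predictors; `p = 13` produces the named
#'   heart-disease schema, other values a generic numeric matrix with
#'   columns `X1..Xp`.
#' @param n_informative Number of informative (class-shifted) continuous
#'   predictors.
#' @param effect_size Standardized mean shift of each informative
#'   predictor between classes.
#' @param class_ratio Length-2 counts, class 0 : class 1 (default the
#'   164:139 balance of the 303-record reference cohort; scaled to `n`).
#' @param missing_rate Completely-at-random missingness fraction applied
#'   to predictors, in \[0, 1).
#' @param seed Integer seed.
#' @return A `tabular_spec` list.
#' @export
tabular_spec <- function(n = 303L, p = 13L, n_informative = 2L,
                         effect_size = 2.0, class_ratio = c(164, 139),
                         missing_rate = 0, seed = 1L) {
  stopifnot(n >= 2, p >= 1, n_informative >= 0, n_informative <= p,
            length(class_ratio) == 2, all(class_ratio > 0),
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "tabular_spec")
}

#' Generate a synthetic tabular cohort
#'
#' Labels are allocated deterministically per `class_ratio` (for
#' `n = 303` and ratio 164:139, exactly 164 zeros and 139 ones).
#' Informative continuous predictors get a between-class mean shift of
#' `effect_size` standard deviations; all other predictors are
#' class-independent noise. With the 13-column schema, categorical
#' attributes are sampled over their legal supports, diseased records
#' receive a severity grade 1-4, and missingness is injected completely
#' at random (never on the outcome).
#'
#' @param spec A [tabular_spec()].
#' @return List with `records` (a `heart_records` data frame when
#'   `p = 13`, else `NULL`), `X` (complete numeric matrix before
#'   missingness), `y` (0/1 labels), `num` (graded outcome) and
#'   `informative` (logical mask of informative columns).
#' @export
gen_tabular <- function(spec = tabular_spec()) {
  stopifnot(inherits(spec, "tabular_spec"))
  n0 <- round(spec$n * spec$class_ratio[1] / sum(spec$class_ratio))
  n1 <- spec$n - n0
  if (n0 < 1 || n1 < 1) stop("class ratio impossible for n", call. = FALSE)
  y <- c(rep(0L, n0), rep(1L, n1))
  with_seed(spec$seed, {
    y <- sample(y)
    shift <- spec$effect_size * (y - mean(y))  # standardized, centered
    if (spec$p == 13L) {
      predictors <- setdiff(UCI_COLUMNS, "num")
      cont <- CONTINUOUS_FIELDS
      informative_cols <- cont[seq_len(min(spec$n_informative,
                                           length(cont)))]
      X <- matrix(0, nrow = spec$n, ncol = 13L,
                  dimnames = list(NULL, predictors))
      for (f in cont) {
        m <- TABULAR_MARGINALS[[f]]
        mu <- m[["mean"]]
        if (f %in% informative_cols) {
          dir <- if (f == "thalach") -1 else 1  # higher risk, lower peak HR
          mu <- mu + dir * m[["sd"]] * spec$effect_size * (y - 0.5)
        }
        X[, f] <- stats::rnorm(spec$n, mean = mu, sd = m[["sd"]])
      }
      X[, "age"] <- round(pmax(X[, "age"], 25))
      X[, "trestbps"] <- round(pmax(X[, "trestbps"], 80))
      X[, "chol"] <- round(pmax(X[, "chol"], 100))
      X[, "thalach"] <- round(pmax(X[, "thalach"], 60))
      X[, "oldpeak"] <- round(pmax(X[, "oldpeak"], 0), 1)
      for (f in setdiff(predictors, cont)) {
        X[, f] <- sample(UCI_SUPPORTS[[f]], spec$n, replace = TRUE)
      }
      informative <- predictors %in% informative_cols
      num <- ifelse(y == 1L, sample(1:4, spec$n, replace = TRUE), 0L)
      df <- as.data.frame(X)
      df$num <- num
      if (spec$missing_rate > 0) {
        for (f in predictors) {
          hit <- stats::runif(spec$n) < spec$missing_rate
          df[[f]][hit] <- NA
        }
      }
      records <- new_heart_records(df, source = "synthetic")
      list(records = records, X = X, y = y, num = num,
           informative = stats::setNames(informative, predictors))
    } else {
      X <- matrix(stats::rnorm(spec$n * spec$p), nrow = spec$n,
                  dimnames = list(NULL, paste0("X", seq_len(spec$p))))
      informative <- seq_len(spec$p) <= spec$n_informative
      X[, informative] <- X[, informative, drop = FALSE] + shift
      list(records = NULL, X = X, y = y, num = y,
           informative = stats::setNames(informative, colnames(X)))
    }
  })
}

#' Specification of a synthetic RR-interval series
#'
#' @param n_beats Number of intervals.
#' @param mean_rr Mean RR interval in seconds.
#' @param sd_rr Interval standard deviation in seconds; the positivity
#'   margin `mean_rr > 3 * sd_rr` must hold.
#' @param seed Integer seed.
#' @return An `rr_spec` list.
#' @export
rr_spec <- function(n_beats = 300L, mean_rr = 0.8, sd_rr = 0.05,
                    seed = 1L) {
  stopifnot(n_beats >= 1, mean_rr > 0, sd_rr >= 0)
  if (mean_rr <= 3 * sd_rr) {
    stop("positivity margin violated: need mean_rr > 3 * sd_rr",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "rr_spec")
}

#' Generate a synthetic RR-interval series
#'
#' Gaussian intervals truncated away from zero (resampled below
#' `mean_rr / 10`), so all values are positive and the sample mean and
#' sd approach the spec at large n.
#'
#' @param spec An [rr_spec()].
#' @return Numeric vector of RR intervals in seconds.
#' @export
gen_rr_series <- function(spec = rr_spec()) {
  stopifnot(inherits(spec, "rr_spec"))
  with_seed(spec$seed, {
    rr <- stats::rnorm(spec$n_beats, spec$mean_rr, spec$sd_rr)
    floor_v <- spec$mean_rr / 10
    while (any(rr < floor_v)) {
      rr[rr < floor_v] <- stats::rnorm(sum(rr < floor_v), spec$mean_rr,
                                       spec$sd_rr)
    }
    rr
  })
}
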