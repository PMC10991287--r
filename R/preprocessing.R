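CONTINUOUS_FIELDS <- c("age", "trestbps", "chol", "thalach", "oldpeak")

#' Cohort specification for similarity-based imputation
#'
#' Missing values are filled from "cohort peers": patients whose age
#' category, cholesterol level and resting blood pressure agree with the
#' incomplete record. Age agrees when both fall in the same bin of
#' `age_bin_width` years; chol and trestbps agree when both fall in the
#' same sample quartile. A peer qualifies when at least `match_quorum` of
#' the similarity fields agree.
#'
#' @param age_bin_width Age bin width in years (> 0).
#' @param similarity_fields Fields used to define the cohort.
#' @param match_quorum Fraction of similarity fields that must agree,
#'   in (0, 1].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(age_bin_width = 10,
                        similarity_fields = c("age", "chol", "trestbps"),
                        match_quorum = 0.5) {
  stopifnot(age_bin_width > 0, match_quorum > 0, match_quorum <= 1,
            all(similarity_fields %in% UCI_COLUMNS))
  structure(list(age_bin_width = age_bin_width,
                 similarity_fields = similarity_fields,
                 match_quorum = match_quorum),
            class = "cohort_spec")
}

# Map a similarity field to discrete bins: age by fixed-width bins,
# everything else by sample quartile. NA stays NA.
similarity_bins <- function(values, field, spec) {
  if (field == "age") return(floor(values / spec$age_bin_width))
  obs <- values[!is.na(values)]
  if (!length(obs)) return(rep(NA_real_, length(values)))
  qs <- unique(stats::quantile(obs, probs = c(0.25, 0.5, 0.75), names = FALSE))
  findInterval(values, qs, left.open = FALSE)
}

#' Impute missing fields from cohort peers
#'
#' Each missing value is replaced by the cohort mode (categorical fields)
#' or cohort mean (continuous fields) over records similar to the patient
#' per `spec`; when no cohort peer observes the field the global
#' mode/mean is used. Observed values are never altered.
#'
#' @param records A `heart_records` data frame.
#' @param spec A [cohort_spec()].
#' @return The records with no remaining missing values.
#' @export
impute_missing <- function(records, spec = cohort_spec()) {
  stopifnot(is.data.frame(records), inherits(spec, "cohort_spec"))
  if (!nrow(records) || !anyNA(records)) return(records)
  fields_missing <- names(records)[vapply(records, anyNA, logical(1))]
  all_missing <- fields_missing[vapply(records[fields_missing],
                                       function(v) all(is.na(v)), logical(1))]
  if (length(all_missing)) {
    stop("field(s) missing in every record: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  bins <- vapply(spec$similarity_fields,
                 function(f) similarity_bins(records[[f]], f, spec),
                 numeric(nrow(records)))
  if (nrow(records) == 1L) bins <- matrix(bins, nrow = 1L)
  quorum_n <- ceiling(spec$match_quorum * length(spec$similarity_fields))
  out <- records
  for (field in fields_missing) {
    categorical <- field %in% names(UCI_SUPPORTS)
    observed <- !is.na(records[[field]])
    for (i in which(is.na(records[[field]]))) {
      agree <- sweep(bins, 2L, bins[i, ], FUN = function(a, b)
        !is.na(a) & !is.na(b) & a == b)
      peers <- which(rowSums(agree) >= quorum_n & observed &
                     seq_len(nrow(records)) != i)
      pool <- records[[field]][if (length(peers)) peers else which(observed)]
      out[[field]][i] <- if (categorical) {
        tab <- table(pool)
        as.numeric(names(tab)[which.max(tab)])
      } else {
        mean(pool)
      }
    }
  }
  out
}

#' Drop exact duplicate records
#'
#' Records equal on all 14 fields (including missing flags) are reduced to
#' their first occurrence; order is otherwise preserved.
#'
#' @param records A `heart_records` data frame.
#' @return The deduplicated records.
#' @export
deduplicate <- function(records) {
  stopifnot(is.data.frame(records))
  out <- records[!duplicated(records), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segregate records by chest-pain category
#'
#' Partitions the cohort into the four chest-pain groups: (1) typical
#' angina, (2) atypical angina, (3) non-anginal pain, (4) asymptomatic.
#'
#' @param records A `heart_records` data frame; every record needs
#'   `cp` observed and in 1..4.
#' @return Named list of four record sets (`"1"` .. `"4"`).
#' @export
segregate_by_chest_pain <- function(records) {
  stopifnot(is.data.frame(records))
  cp <- records$cp
  if (anyNA(cp) || !all(cp %in% 1:4)) {
    stop("chest-pain category must be observed and in {1,2,3,4}",
         call. = FALSE)
  }
  stats::setNames(lapply(1:4, function(g) {
    out <- records[cp == g, , drop = FALSE]
    rownames(out) <- NULL
    out
  }), as.character(1:4))
}

#' Standardize a design matrix
#'
#' Centers each column to mean 0 and rescales to sample standard
#' deviation 1 (n-1 denominator). The returned parameters invert the
#' transform and can be re-applied to new data, so scaling can be fit on
#' training rows only.
#'
#' @param X Numeric matrix with uniquely named columns.
#' @return List with `X` (the scaled matrix) and `params`, a
#'   `scaler_params` object holding per-column means and sds.
#' @export
standard_scale <- function(X) {
  stopifnot(is.matrix(X), !anyNA(X))
  means <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    stop("constant column(s) cannot be scaled: ",
         paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
  }
  params <- structure(list(means = means, sds = sds), class = "scaler_params")
  list(X = apply_scaler(X, params), params = params)
}

#' Apply fitted scaling parameters to new data
#' @param X Numeric matrix conformable with the fitted columns.
#' @param params A `scaler_params` object from [standard_scale()].
#' @return The scaled matrix.
#' @export
apply_scaler <- function(X, params) {
  stopifnot(inherits(params, "scaler_params"), ncol(X) == length(params$means))
  sweep(sweep(X, 2L, params$means, "-"), 2L, params$sds, "/")
}

#' Invert the standardization
#' @inheritParams apply_scaler
#' @return The matrix on its original scales.
#' @export
invert_scaler <- function(X, params) {
  stopifnot(inherits(params, "scaler_params"), ncol(X) == length(params$means))
  sweep(sweep(X, 2L, params$sds, "*"), 2L, params$means, "+")
}

#' Serialize scaling parameters to JSON
#' @param params A `scaler_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaler <- function(params, path) {
  stopifnot(inherits(params, "scaler_params"))
  jsonlite::write_json(list(means = as.list(params$means),
                            sds = as.list(params$sds)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read scaling parameters from JSON
#' @param path Path written by [write_scaler()].
#' @return A `scaler_params` object.
#' @export
read_scaler <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(means = unlist(raw$means), sds = unlist(raw$sds)),
            class = "scaler_params")
}
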