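# Canonical 14-column order of the UCI heart-disease dialect.
# `num` is the graded outcome (0 = no disease, 1-4 = increasing severity).
UCI_COLUMNS <- c(
  "age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
  "thalach", "exang", "oldpeak", "slope", "ca", "thal", "num"
)

# Legal supports for the categorical attributes; continuous attributes are
# only required to be numeric.
UCI_SUPPORTS <- list(
  sex = c(0, 1), cp = 1:4, fbs = c(0, 1), restecg = 0:2,
  exang = c(0, 1), slope = 1:3, ca = 0:3, thal = c(3, 6, 7),
  num = 0:4
)

#' Canonical UCI heart-disease column names
#'
#' Returns the 14 attribute names in the canonical UCI order:
#' thirteen predictors followed by the graded outcome `num`.
#'
#' @return Character vector of length 14.
#' @export
uci_columns <- function() UCI_COLUMNS

#' Parse one line of a UCI-dialect heart-disease file
#'
#' A line holds exactly 14 comma-separated fields; `?` marks a missing
#' value. Fields are parsed on their native scales and categorical fields
#' are checked against their legal supports. The outcome `num` may not be
#' missing.
#'
#' @param line A single character string.
#' @param line_no Line number used in error messages.
#' @return A named list of 14 numeric values with `NA` for missing fields.
#' @examples
#' parse_uci_line("63,1,1,145,233,1,2,150,0,2.3,3,0,6,0")
#' @export
parse_uci_line <- function(line, line_no = 1L) {
  tokens <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
  if (length(tokens) != length(UCI_COLUMNS)) {
    stop(sprintf(
      "line %d: expected %d comma-separated fields, found %d",
      line_no, length(UCI_COLUMNS), length(tokens)
    ), call. = FALSE)
  }
  if (any(tokens == "")) {
    stop(sprintf("line %d: empty field (only '?' marks missing values)",
                 line_no), call. = FALSE)
  }
  values <- rep(NA_real_, length(tokens))
  obs <- tokens != "?"
  parsed <- suppressWarnings(as.numeric(tokens[obs]))
  if (anyNA(parsed)) {
    bad <- tokens[obs][is.na(parsed)][1]
    stop(sprintf("line %d: non-numeric token '%s'", line_no, bad),
         call. = FALSE)
  }
  values[obs] <- parsed
  names(values) <- UCI_COLUMNS
  if (is.na(values[["num"]])) {
    stop(sprintf("line %d: outcome 'num' may not be missing", line_no),
         call. = FALSE)
  }
  for (field in names(UCI_SUPPORTS)) {
    v <- values[[field]]
    if (!is.na(v) && !v %in% UCI_SUPPORTS[[field]]) {
      stop(sprintf("line %d: %s = %s outside its legal support",
                   line_no, field, format(v)), call. = FALSE)
    }
  }
  as.list(values)
}

new_heart_records <- function(df, source = "memory") {
  rownames(df) <- NULL
  structure(df, class = c("heart_records", "data.frame"), source = source)
}

#' Read a UCI-dialect heart-disease file
#'
#' One record per non-empty line, original order preserved. Malformed
#' lines are reported together, with their line numbers, in a single error.
#'
#' @param path Path to a comma-separated UCI `.data` style file.
#' @return A `heart_records` data frame (14 numeric columns, `NA` for
#'   missing) with a `source` attribute recording provenance.
#' @export
read_uci_heart <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  parsed <- vector("list", length(keep))
  errors <- character(0)
  for (i in seq_along(keep)) {
    res <- tryCatch(parse_uci_line(lines[keep[i]], line_no = keep[i]),
                    error = function(e) e)
    if (inherits(res, "error")) errors <- c(errors, conditionMessage(res))
    else parsed[[i]] <- res
  }
  if (length(errors)) {
    stop("malformed input:\n", paste(errors, collapse = "\n"), call. = FALSE)
  }
  if (!length(parsed)) {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(UCI_COLUMNS)), UCI_COLUMNS))
    return(new_heart_records(df, source = path))
  }
  df <- do.call(rbind, lapply(parsed, as.data.frame))
  new_heart_records(df, source = path)
}

#' Write records back to the UCI dialect
#'
#' Inverse of [read_uci_heart()]: missing values are written as `?` so a
#' read/write round trip preserves every field and missing flag.
#'
#' @param records A `heart_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_uci_heart <- function(records, path) {
  stopifnot(is.data.frame(records))
  mat <- vapply(UCI_COLUMNS, function(col) {
    v <- records[[col]]
    out <- vapply(v, function(x) {
      if (is.na(x)) "?" else format(x, trim = TRUE, scientific = FALSE)
    }, character(1))
    out
  }, character(nrow(records)))
  if (nrow(records) == 1L) mat <- matrix(mat, nrow = 1L)
  writeLines(apply(mat, 1L, paste, collapse = ","), path)
  invisible(path)
}

#' Binarize the graded outcome
#'
#' Grade 0 means no disease; grades 1-4 all mean disease present.
#'
#' @param num Integer vector with values in 0..4.
#' @return Integer vector of 0/1 labels.
#' @examples
#' binarize_target(c(0, 1, 4))  # 0 1 1
#' @export
binarize_target <- function(num) {
  if (anyNA(num) || !all(num %in% 0:4)) {
    stop("outcome grades must lie in {0,...,4}", call. = FALSE)
  }
  as.integer(num > 0)
}

#' Convert records to a design matrix and label vector
#'
#' Splits a record set into the 13-predictor numeric design matrix and the
#' binarized 0/1 label vector. The matrix must be complete: impute first
#' (see [impute_missing()]).
#'
#' @param records A `heart_records` data frame.
#' @return A list with `X` (n x 13 named matrix) and `y` (0/1 labels).
#' @export
records_matrix <- function(records) {
  predictors <- setdiff(UCI_COLUMNS, "num")
  X <- as.matrix(records[, predictors, drop = FALSE])
  if (anyNA(X)) {
    stop("design matrix contains missing values; run impute_missing() first",
         call. = FALSE)
  }
  storage.mode(X) <- "double"
  rownames(X) <- seq_len(nrow(X))
  list(X = X, y = binarize_target(records$num))
}

#' Load a pipeline configuration file
#'
#' Reads a YAML or JSON configuration into a nested list. Format chosen by
#' file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path Path to the configuration file.
#' @return A nested list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext, call. = FALSE)
}
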