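# Feature extraction for device signals: waveform amplitude/complexity
# statistics and RR-interval (heart-rate-variability) measures.

#' Maximum voltage of a sampled signal
#' @param v Numeric vector of voltage samples (length >= 1).
#' @return The maximum sample.
#' @export
max_voltage <- function(v) {
  if (!length(v)) stop("empty signal has no maximum", call. = FALSE)
  stopifnot(all(is.finite(v)))
  max(v)
}

#' Total harmonic distortion
#'
#' Ratio of the summed harmonic-component magnitudes to the fundamental
#' (filter) power: `sum(hc) / p_ff`.
#'
#' @param hc Nonnegative harmonic component magnitudes.
#' @param p_ff Fundamental/filter power, same units as `hc`, nonzero.
#' @return The THD ratio.
#' @export
total_harmonic_distortion <- function(hc, p_ff) {
  stopifnot(all(hc >= 0))
  if (p_ff == 0) stop("fundamental power must be nonzero", call. = FALSE)
  sum(hc) / p_ff
}

#' Heart rate from an RR interval
#' @param rr_t RR interval in seconds (> 0).
#' @return Heart rate in beats per minute, `60 / rr_t`.
#' @examples
#' heart_rate(0.8)  # 75 bpm
#' @export
heart_rate <- function(rr_t) {
  if (any(rr_t <= 0)) stop("RR interval must be positive", call. = FALSE)
  60 / rr_t
}

#' Zero-crossing rate
#'
#' Fraction of adjacent sample pairs whose sign strictly changes; a pair
#' involving a zero sample counts as "no change".
#'
#' @param v Numeric signal of length >= 2.
#' @return The crossing fraction in \[0, 1\].
#' @export
zero_crossing_rate <- function(v) {
  if (length(v) < 2L) stop("need at least 2 samples", call. = FALSE)
  s <- sign(v)
  changes <- s[-length(s)] * s[-1] < 0
  sum(changes) / length(changes)
}

#' Entropy of a gridded probability distribution
#'
#' Two conventions are provided. `"shannon"` (the default for pipeline
#' use) is the standard `-sum(P * log(P))` in nats. `"as_printed"`
#' evaluates the literal ratio form `sum(P / log(P))`, which is negative
#' for all proper distributions and undefined when any cell equals 1;
#' it is kept for exact comparison with the ratio convention. Zero cells
#' contribute zero in both modes.
#'
#' @param p Nonnegative cell probabilities summing to 1 (within 1e-9).
#' @param mode `"shannon"` or `"as_printed"`.
#' @return The entropy value in nats.
#' @export
grid_entropy <- function(p, mode = c("shannon", "as_printed")) {
  mode <- match.arg(mode)
  p <- as.numeric(p)
  stopifnot(all(p >= 0), all(p <= 1))
  if (abs(sum(p) - 1) > 1e-9) {
    stop("cell probabilities must sum to 1", call. = FALSE)
  }
  nz <- p[p > 0]
  if (mode == "shannon") return(-sum(nz * log(nz)))
  if (any(nz == 1)) {
    stop("degenerate distribution: log(1) = 0 denominator", call. = FALSE)
  }
  sum(nz / log(nz))
}

#' Energy of a gridded probability distribution
#'
#' `sum(P^2)`; equals 1 only when all mass sits in one cell.
#'
#' @inheritParams grid_entropy
#' @return The energy in (0, 1].
#' @export
grid_energy <- function(p) {
  p <- as.numeric(p)
  stopifnot(all(p >= 0), all(p <= 1))
  if (abs(sum(p) - 1) > 1e-9) {
    stop("cell probabilities must sum to 1", call. = FALSE)
  }
  sum(p^2)
}

check_rr <- function(rr) {
  if (length(rr) < 2L) stop("need at least 2 RR intervals", call. = FALSE)
  stopifnot(all(rr > 0), all(is.finite(rr)))
}

#' Mean successive RR difference
#'
#' Average signed difference between consecutive RR intervals over the
#' M - 1 adjacent pairs.
#'
#' @param rr Positive RR intervals in seconds, length M >= 2.
#' @return The mean successive difference `k`.
#' @export
rr_deviation_mean <- function(rr) {
  check_rr(rr)
  mean(diff(rr))
}

#' RR variability (scaled successive-difference spread)
#'
#' `(1/M) * sqrt(sum((diff - k)^2))` where `k` is the mean successive
#' difference from [rr_deviation_mean()]. Note the 1/M prefactor sits
#' outside the square root, so this is not the usual SDSD.
#'
#' @inheritParams rr_deviation_mean
#' @return The spread statistic.
#' @export
rr_sd <- function(rr) {
  check_rr(rr)
  d <- diff(rr)
  sqrt(sum((d - mean(d))^2)) / length(rr)
}

#' Root-mean-square of successive RR differences
#'
#' `"rmssd"` (the default for pipeline use) is the standard HRV statistic
#' `sqrt(mean(diff^2))` over the M - 1 successive differences.
#' `"as_printed"` evaluates the literal unsquared form
#' `sqrt(sum(diff) / (M - 1))`, which is undefined when the summed
#' differences are negative; it is kept for exact comparison with that
#' convention.
#'
#' @inheritParams rr_deviation_mean
#' @param mode `"rmssd"` or `"as_printed"`.
#' @return The root-mean-square statistic.
#' @export
rr_rms_successive <- function(rr, mode = c("rmssd", "as_printed")) {
  mode <- match.arg(mode)
  check_rr(rr)
  d <- diff(rr)
  if (mode == "rmssd") return(sqrt(sum(d^2) / length(d)))
  s <- sum(d) / length(d)
  if (s < 0) {
    stop("unsquared form undefined: successive differences sum below zero",
         call. = FALSE)
  }
  sqrt(s)
}

#' Extract the full signal-feature block
#'
#' Convenience wrapper assembling the waveform and RR-interval features
#' into one named vector, using the corrected (`shannon` / `rmssd`)
#' conventions.
#'
#' @param v Voltage samples (length >= 2).
#' @param rr RR intervals in seconds (length >= 2).
#' @param hc Harmonic component magnitudes.
#' @param p_ff Fundamental power.
#' @param grid_p Optional gridded probabilities for entropy/energy;
#'   defaults to the normalized histogram of `v` over 8 bins.
#' @return Named numeric vector: `v_max`, `thd`, `heart_rate`, `zcr`,
#'   `entropy`, `energy`, `sd_rr`, `rms_succ`.
#' @export
signal_features <- function(v, rr, hc = numeric(0), p_ff = 1,
                            grid_p = NULL) {
  if (is.null(grid_p)) {
    counts <- tabulate(cut(v, breaks = 8, labels = FALSE), nbins = 8)
    grid_p <- counts / sum(counts)
  }
  c(v_max = max_voltage(v),
    thd = total_harmonic_distortion(hc, p_ff),
    heart_rate = heart_rate(mean(rr)),
    zcr = zero_crossing_rate(v),
    entropy = grid_entropy(grid_p, mode = "shannon"),
    energy = grid_energy(grid_p),
    sd_rr = rr_sd(rr),
    rms_succ = rr_rms_successive(rr, mode = "rmssd"))
}

#' Read a one-sample-per-line signal file
#' @param path Text file with one numeric sample per line.
#' @return Numeric vector.
#' @export
read_signal_series <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  as.numeric(readLines(path, warn = FALSE))
}
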