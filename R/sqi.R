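#' Skewness signal quality index
#'
#' Sample skewness of an amplitude vector, using the moment form
#' \deqn{S = \frac{1}{N}\sum_{i=1}^{N}\left(\frac{x_i - \hat\mu}{\sigma}\right)^3}
#' with the population (1/N) standard deviation. Asymmetric pulsatile PPG
#' beats give positive skewness; symmetric noise gives values near zero, so
#' the statistic serves as a cheap signal quality index.
#'
#' The statistic is invariant under positive affine transforms
#' `a * x + b` (a > 0) and changes sign under `x -> -x`. A constant vector has
#' no defined skewness; by convention 0 is returned with a warning so that
#' batch runs over pathological filter outputs never abort.
#'
#' @param x Numeric vector, length >= 2, finite.
#' @param sd_estimator `"population"` (1/N, the default, matching the moment
#'   definition above) or `"sample"` (1/(N-1)).
#' @return Dimensionless skewness value.
#' @examples
#' ppg_skewness(c(0, 0, 1)) # sqrt(2)/2
#' @export
ppg_skewness <- function(x, sd_estimator = c("population", "sample")) {
  sd_estimator <- match.arg(sd_estimator)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) {
    stop("skewness requires at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("skewness requires finite samples", call. = FALSE)
  }
  d <- x - mean(x)
  denom <- if (sd_estimator == "population") n else n - 1L
  s <- sqrt(sum(d^2) / denom)
  if (s == 0) {
    warning("constant signal: skewness undefined, returning 0", call. = FALSE)
    return(0)
  }
  mean((d / s)^3)
}

#' Windowed record-level signal quality index
#'
#' Partitions a record into consecutive non-overlapping windows of
#' `round(window_len_s * fs)` samples starting at sample 1; a trailing
#' remainder shorter than one window is discarded. The record-level SQI is
#' the maximum of the per-window skewness values.
#'
#' @param record A [ppg_record()].
#' @param window_len_s Window length in seconds (default 1).
#' @param sd_estimator Passed to [ppg_skewness()].
#' @return An object of class `sqi_result`: list with `per_window` (skewness
#'   per window), `record_sqi` (their maximum), `window_len_s`, `n_windows`.
#' @examples
#' r <- ppg_record(rexp(2100), fs = 1000)
#' windowed_sqi(r)$n_windows # 2; the trailing 100 samples are dropped
#' @export
windowed_sqi <- function(record, window_len_s = 1.0,
                         sd_estimator = c("population", "sample")) {
  stopifnot(inherits(record, "ppg_record"))
  sd_estimator <- match.arg(sd_estimator)
  if (!is.numeric(window_len_s) || length(window_len_s) != 1L ||
      window_len_s <= 0) {
    stop("'window_len_s' must be a positive scalar", call. = FALSE)
  }
  w <- round(window_len_s * record$fs)
  n <- length(record$samples)
  if (w < 2L) {
    stop("window of ", w, " samples is too short for skewness", call. = FALSE)
  }
  if (n < w) {
    stop(sprintf("record (%d samples) shorter than one %g-s window (%d samples)",
                 n, window_len_s, w), call. = FALSE)
  }
  n_windows <- as.integer(n %/% w)
  per_window <- vapply(seq_len(n_windows), function(k) {
    ppg_skewness(record$samples[((k - 1L) * w + 1L):(k * w)],
                 sd_estimator = sd_estimator)
  }, numeric(1))
  structure(
    list(per_window = per_window, record_sqi = max(per_window),
         window_len_s = window_len_s, n_windows = n_windows),
    class = "sqi_result"
  )
}

#' @export
print.sqi_result <- function(x, ...) {
  cat(sprintf("<sqi_result> record SQI %.4f over %d window(s) of %g s: %s\n",
              x$record_sqi, x$n_windows, x$window_len_s,
              paste(sprintf("%.4f", x$per_window), collapse = ", ")))
  invisible(x)
}
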