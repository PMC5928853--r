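# Maximal-overlap discrete wavelet transform (MODWT) denoising with the
# db2 (Daubechies 4-tap) wavelet.
#
# The MODWT is the non-decimated, shift-invariant form of the DWT: at level
# j the scaling/wavelet filters (rescaled by 1/sqrt(2)) are upsampled by
# 2^(j-1) and applied circularly. Implemented in the frequency domain, where
# upsampling is index dilation of the filter DFT and synthesis uses the
# conjugate filters; the analysis operator is an isometry
# (|H(f)|^2 + |G(f)|^2 = 1), so reconstruction is exact to rounding.

# db2 scaling filter (sums to sqrt(2)); wavelet filter by the QMF relation
db2_filters <- function() {
  h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)
  list(h = h / sqrt(2), g = g / sqrt(2))
}

modwt_filter_dfts <- function(n) {
  f <- db2_filters()
  list(H = stats::fft(c(f$h, rep(0, n - 4L))),
       G = stats::fft(c(f$g, rep(0, n - 4L))))
}

#' Maximal-overlap discrete wavelet transform (db2)
#'
#' Circular (periodic-boundary) MODWT of a series, to `level` levels.
#'
#' @param x Numeric vector, length >= 4.
#' @param level Decomposition depth J, `1 <= J <= floor(log2(length(x)))`.
#' @return List with `W` (list of J detail-coefficient vectors, each
#'   `length(x)` long) and `V` (the level-J smooth).
#' @seealso [imodwt()], [modwt_denoise()]
#' @export
modwt <- function(x, level) {
  n <- length(x)
  if (n < 4L) stop("modwt requires at least 4 samples", call. = FALSE)
  level <- as.integer(level)
  if (level < 1L || level > floor(log2(n))) {
    stop(sprintf("level must be in 1..%d for a series of length %d",
                 floor(log2(n)), n), call. = FALSE)
  }
  flt <- modwt_filter_dfts(n)
  Vf <- stats::fft(as.numeric(x))
  W <- vector("list", level)
  for (j in seq_len(level)) {
    idx <- ((0:(n - 1L)) * 2^(j - 1L)) %% n + 1L
    W[[j]] <- Re(stats::fft(flt$G[idx] * Vf, inverse = TRUE)) / n
    Vf <- flt$H[idx] * Vf
  }
  list(W = W, V = Re(stats::fft(Vf, inverse = TRUE)) / n)
}

#' Inverse MODWT (db2)
#'
#' @param w A decomposition as returned by [modwt()] (fields `W`, `V`).
#' @return The reconstructed series.
#' @export
imodwt <- function(w) {
  n <- length(w$V)
  J <- length(w$W)
  flt <- modwt_filter_dfts(n)
  Vf <- stats::fft(as.numeric(w$V))
  for (j in rev(seq_len(J))) {
    idx <- ((0:(n - 1L)) * 2^(j - 1L)) %% n + 1L
    Vf <- Conj(flt$H[idx]) * Vf +
      Conj(flt$G[idx]) * stats::fft(as.numeric(w$W[[j]]))
  }
  Re(stats::fft(Vf, inverse = TRUE)) / n
}

#' Wavelet denoising via MODWT soft thresholding
#'
#' Reflection-extends the series (to avoid circular wrap-around artifacts),
#' computes the db2 MODWT to `level` levels, soft-thresholds each detail
#' level with the level-dependent universal threshold
#' \eqn{t_j = \hat\sigma_j \sqrt{2 \log N}} where \eqn{\hat\sigma_j} is the
#' median absolute deviation of that level's coefficients divided by 0.6745,
#' and reconstructs.
#'
#' @param x Numeric vector.
#' @param level Decomposition depth.
#' @return Denoised vector, same length as `x`.
#' @export
modwt_denoise <- function(x, level) {
  n <- length(x)
  ext <- c(x, rev(x))
  w <- modwt(ext, level)
  thr_scale <- sqrt(2 * log(length(ext)))
  for (j in seq_len(level)) {
    d <- w$W[[j]]
    sigma <- stats::median(abs(d)) / 0.6745
    t <- sigma * thr_scale
    w$W[[j]] <- sign(d) * pmax(abs(d) - t, 0)
  }
  imodwt(w)[seq_len(n)]
}
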