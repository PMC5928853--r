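# Least-squares linear-phase FIR bandpass design.
#
# Even-order (odd tap count) type-I design: the amplitude response is
# A(w) = sum_{k=0}^{M} c_k cos(k w), M = order/2, and the integrated squared
# error against a piecewise-constant desired response (0 on the stopbands,
# 1 on the passband, transition bands don't-care) is minimized in closed
# form via the normal equations
#   Q c = d,  Q[k,l] = sum_b int_b cos(kw) cos(lw) dw,
#             d[k]   = sum_b D_b int_b cos(kw) dw.
# Taps follow as h[M+1] = c_0, h[M+1 +/- k] = c_k / 2.

# int_{w1}^{w2} cos(m w) dw, vectorized over m (m = 0 handled exactly)
cos_moment <- function(m, w1, w2) {
  out <- numeric(length(m))
  z <- m == 0
  out[z] <- w2 - w1
  out[!z] <- (sin(m[!z] * w2) - sin(m[!z] * w1)) / m[!z]
  out
}

firls_bandpass <- function(order, fs, f_stop_lo, f_pass_lo, f_pass_hi,
                           f_stop_hi) {
  if (order %% 2L != 0L) {
    stop("firls_bandpass requires an even filter order", call. = FALSE)
  }
  nyq <- fs / 2
  if (!(0 <= f_stop_lo && f_stop_lo < f_pass_lo && f_pass_lo < f_pass_hi &&
        f_pass_hi < f_stop_hi && f_stop_hi <= nyq)) {
    stop("band edges must satisfy 0 <= stop_lo < pass_lo < pass_hi < stop_hi <= fs/2",
         call. = FALSE)
  }
  M <- order %/% 2L
  w <- pi * c(0, f_stop_lo, f_pass_lo, f_pass_hi, f_stop_hi, nyq) / nyq
  bands <- list(c(w[1], w[2], 0), c(w[3], w[4], 1), c(w[5], w[6], 0))
  k <- 0:M
  Q <- matrix(0, M + 1L, M + 1L)
  d <- numeric(M + 1L)
  for (b in bands) {
    dif <- outer(k, k, "-")
    sm <- outer(k, k, "+")
    Q <- Q + 0.5 * (matrix(cos_moment(as.vector(dif), b[1], b[2]), M + 1L) +
                    matrix(cos_moment(as.vector(sm), b[1], b[2]), M + 1L))
    d <- d + b[3] * cos_moment(k, b[1], b[2])
  }
  cvec <- solve(Q, d)
  h <- numeric(order + 1L)
  h[M + 1L] <- cvec[1L]
  if (M > 0L) {
    h[M + 1L + seq_len(M)] <- cvec[-1L] / 2
    h[M + 1L - seq_len(M)] <- cvec[-1L] / 2
  }
  h
}
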