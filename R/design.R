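#' Passband specification
#'
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high`. Feasibility
#'   against a sampling rate (`f_high < fs/2`) is checked at design time.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(f_low, f_high) {
  if (!is.numeric(f_low) || !is.numeric(f_high) ||
      !is.finite(f_low) || !is.finite(f_high) ||
      f_low <= 0 || f_high <= f_low) {
    stop("band requires 0 < f_low < f_high (Hz)", call. = FALSE)
  }
  structure(list(f_low = as.numeric(f_low), f_high = as.numeric(f_high)),
            class = "band_spec")
}

#' Filter families and their order grids
#'
#' The bank spans nine families, each swept over ten orders. "Order" means
#' the family's natural size parameter: a window length in seconds for the
#' moving-average, median and FIR designs; the design-function order argument
#' for the IIR bandpass designs (note a bandpass of design order N has
#' effective order 2N); the decomposition level for the wavelet denoiser.
#'
#' @return Named list of numeric grids, one per family, in canonical family
#'   order.
#' @export
family_grids <- function() {
  win <- seq(0.05, 0.50, by = 0.05)
  list(
    moving_average = win,
    median         = win,
    fir_hamming    = win,
    fir_ls         = win,
    butterworth    = seq(2, 20, by = 2),
    cheby1         = seq(2, 20, by = 2),
    cheby2         = seq(2, 20, by = 2),
    elliptic       = seq(2, 20, by = 2),
    wavelet        = 1:10
  )
}

#' Construct a filter specification
#'
#' @param family One of `names(family_grids())`.
#' @param order_param The family's order parameter (seconds, design order, or
#'   wavelet level; see [family_grids()]).
#' @param passband_ripple_db Passband ripple in dB (cheby1 and elliptic;
#'   default 0.1).
#' @param stopband_atten_db Stopband attenuation in dB (cheby2 default 20,
#'   elliptic default 30).
#' @param check_grid If `TRUE` (default), `order_param` must lie on the
#'   family's published grid; set `FALSE` to design off-grid configurations.
#' @return An object of class `ppg_filter_spec`.
#' @export
filter_spec <- function(family, order_param,
                        passband_ripple_db = NULL,
                        stopband_atten_db = NULL,
                        check_grid = TRUE) {
  grids <- family_grids()
  family <- match.arg(family, names(grids))
  if (!is.numeric(order_param) || length(order_param) != 1L ||
      !is.finite(order_param)) {
    stop("'order_param' must be a finite scalar", call. = FALSE)
  }
  if (check_grid && !any(abs(grids[[family]] - order_param) < 1e-9)) {
    stop(sprintf("order %g is off the %s grid {%s}; use check_grid = FALSE to force",
                 order_param, family,
                 paste(grids[[family]], collapse = ", ")), call. = FALSE)
  }
  if (is.null(passband_ripple_db)) {
    passband_ripple_db <- if (family %in% c("cheby1", "elliptic")) 0.1 else NA_real_
  }
  if (is.null(stopband_atten_db)) {
    stopband_atten_db <- switch(family, cheby2 = 20, elliptic = 30, NA_real_)
  }
  structure(
    list(family = family, order_param = order_param,
         passband_ripple_db = passband_ripple_db,
         stopband_atten_db = stopband_atten_db),
    class = "ppg_filter_spec"
  )
}

#' @export
print.ppg_filter_spec <- function(x, ...) {
  extras <- c(
    if (is.finite(x$passband_ripple_db)) sprintf("Rp=%g dB", x$passband_ripple_db),
    if (is.finite(x$stopband_atten_db)) sprintf("Rs=%g dB", x$stopband_atten_db)
  )
  cat(sprintf("<ppg_filter_spec> %s, order %g%s\n", x$family, x$order_param,
              if (length(extras)) paste0(" (", paste(extras, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Enumerate the full filter bank
#'
#' @return A list of exactly 90 [filter_spec()] objects: 9 families x 10
#'   orders, in canonical family order then ascending order parameter.
#' @param families Optional character vector restricting to a subset of
#'   families.
#' @export
enumerate_bank <- function(families = names(family_grids())) {
  grids <- family_grids()
  families <- match.arg(families, names(grids), several.ok = TRUE)
  specs <- list()
  for (fam in names(grids)[names(grids) %in% families]) {
    for (ord in grids[[fam]]) {
      specs[[length(specs) + 1L]] <- filter_spec(fam, ord)
    }
  }
  specs
}

# ---- analog lowpass prototypes (zero-pole-gain, cutoff 1 rad/s) ----------

butter_prototype <- function(n) {
  k <- seq_len(n)
  list(zero = complex(0), pole = exp(1i * pi * (2 * k + n - 1) / (2 * n)),
       gain = 1)
}

cheby1_prototype <- function(n, rp_db) {
  eps <- sqrt(10^(rp_db / 10) - 1)
  mu <- asinh(1 / eps) / n
  theta <- (2 * seq_len(n) - 1) * pi / (2 * n)
  p <- -sinh(mu) * sin(theta) + 1i * cosh(mu) * cos(theta)
  g <- Re(prod(-p))
  if (n %% 2L == 0L) g <- g / sqrt(1 + eps^2)
  list(zero = complex(0), pole = p, gain = g)
}

cheby2_prototype <- function(n, rs_db) {
  de <- 1 / sqrt(10^(rs_db / 10) - 1)
  mu <- asinh(1 / de) / n
  theta <- (2 * seq_len(n) - 1) * pi / (2 * n)
  z <- 1i / cos(theta)
  z <- z[is.finite(z)] # odd n: one zero escapes to infinity
  p <- 1 / (-sinh(mu) * sin(theta) + 1i * cosh(mu) * cos(theta))
  g <- Re(prod(-p) / prod(-z))
  list(zero = z, pole = p, gain = g)
}

elliptic_prototype <- function(n, rp_db, rs_db) {
  ncauer <- get("ncauer", envir = asNamespace("signal"))
  z <- ncauer(rp_db, rs_db, n)
  list(zero = z$zero, pole = z$pole, gain = z$gain)
}

# ---- zpk -> second-order sections ----------------------------------------

# Group roots into real coefficient pairs: complex roots with their
# conjugates, real roots paired outermost-with-innermost (so e.g. the z=+1
# and z=-1 bandpass zeros share a section).
split_conjugate_pairs <- function(r, tol = 1e-8) {
  is_real <- abs(Im(r)) <= tol * pmax(1, Mod(r))
  cx <- r[!is_real & Im(r) > 0]
  n_neg <- sum(!is_real & Im(r) < 0)
  if (length(cx) != n_neg) {
    stop("complex roots do not come in conjugate pairs", call. = FALSE)
  }
  re <- sort(Re(r[is_real]))
  if (length(re) %% 2L) {
    stop("odd number of real roots; only even-order designs are supported",
         call. = FALSE)
  }
  pairs <- lapply(cx, function(z) c(z, Conj(z)))
  i <- 1L
  j <- length(re)
  while (i < j) {
    pairs[[length(pairs) + 1L]] <- complex(real = c(re[i], re[j]),
                                           imaginary = c(0, 0))
    i <- i + 1L
    j <- j - 1L
  }
  pairs
}

# Pair each pole pair (nearest the unit circle first) with the closest
# remaining zero pair; distribute gain evenly; order sections with the
# least-damped poles last.
zpk_to_sos <- function(zeros, poles, gain) {
  if (length(zeros) != length(poles)) {
    stop("zpk_to_sos expects equal zero and pole counts", call. = FALSE)
  }
  zp <- split_conjugate_pairs(zeros)
  pp <- split_conjugate_pairs(poles)
  pmod <- vapply(pp, function(p) max(Mod(p)), numeric(1))
  pp <- pp[order(pmod, decreasing = TRUE)]
  ns <- length(pp)
  sections <- vector("list", ns)
  for (i in seq_len(ns)) {
    p <- pp[[i]]
    d <- vapply(zp, function(z) {
      min(Mod(p[1] - z[1]) + Mod(p[2] - z[2]),
          Mod(p[1] - z[2]) + Mod(p[2] - z[1]))
    }, numeric(1))
    k <- which.min(d)
    sections[[i]] <- list(p = p, z = zp[[k]])
    zp <- zp[-k]
  }
  gmag <- abs(gain)^(1 / ns)
  sos <- t(vapply(sections, function(s) {
    b <- gmag * c(1, -Re(s$z[1] + s$z[2]), Re(s$z[1] * s$z[2]))
    a <- c(1, -Re(s$p[1] + s$p[2]), Re(s$p[1] * s$p[2]))
    c(b, a)
  }, numeric(6)))
  sos[1L, 1:3] <- sos[1L, 1:3] * sign(gain)
  sos <- sos[rev(seq_len(ns)), , drop = FALSE]
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

sos_pole_moduli <- function(sos) {
  apply(sos, 1L, function(s) max(Mod(polyroot(rev(s[4:6])))))
}

design_iir_bandpass <- function(prototype, fs, band) {
  # bilinear prewarp so the band edges land exactly
  T <- 2
  W <- (2 / T) * tan(pi * c(band$f_low, band$f_high) / fs)
  proto <- signal::Zpg(zero = prototype$zero, pole = prototype$pole,
                       gain = prototype$gain)
  dig <- signal::bilinear(signal::sftrans(proto, W = W, stop = FALSE), T = T)
  g <- dig$gain
  if (is.complex(g)) {
    if (abs(Im(g)) > 1e-8 * max(1, abs(Re(g)))) {
      stop("design error: complex overall gain", call. = FALSE)
    }
    g <- Re(g)
  }
  sos <- zpk_to_sos(dig$zero, dig$pole, g)
  if (any(sos_pole_moduli(sos) >= 1)) {
    stop("design error: unstable IIR realization (pole on or outside the unit circle)",
         call. = FALSE)
  }
  sos
}

# force a sample count odd for symmetric, phase-free sliding windows
odd_window <- function(len_s, fs) {
  n <- round(len_s * fs)
  if (n %% 2L == 0L) n <- n + 1L
  as.integer(max(n, 1L))
}

#' Design one filter configuration
#'
#' Realizes a [filter_spec()] at a sampling rate and passband:
#' * IIR families (`butterworth`, `cheby1`, `cheby2`, `elliptic`): bandpass
#'   design of design order `order_param` (effective order `2 * order_param`),
#'   returned as a stable cascade of second-order sections.
#' * `fir_hamming`: Hamming-window bandpass with `round(order_param * fs) + 1`
#'   taps.
#' * `fir_ls`: least-squares linear-phase bandpass, same tap rule, with
#'   stopband edges at `f_low - 0.2` Hz and `f_high + 2` Hz (the lower edge
#'   is clamped to `f_low / 2`, with a warning, if it would be non-positive).
#' * `moving_average` / `median`: centered sliding window of
#'   `round(order_param * fs)` samples, forced odd.
#' * `wavelet`: MODWT (db2) denoiser at decomposition level `order_param`
#'   with level-dependent universal soft thresholds.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param band A [band_spec()]; ignored by the procedural families
#'   (moving average, median, wavelet).
#' @return An object of class `ppg_filter` with fields `spec`, `kind`
#'   (`"linear_iir"`, `"linear_fir"` or `"procedural"`), coefficients (`sos`
#'   matrix or `taps` vector or procedure parameters), `fs`, `band`,
#'   `effective_order`.
#' @examples
#' f <- design_filter(filter_spec("cheby2", 4), fs = 1000, band_spec(0.5, 8))
#' nrow(f$sos) # 4 biquads (effective order 8)
#' @export
design_filter <- function(spec, fs, band = band_spec(0.5, 8)) {
  stopifnot(inherits(spec, "ppg_filter_spec"))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive scalar (Hz)", call. = FALSE)
  }
  uses_band <- spec$family %in% c("fir_hamming", "fir_ls", "butterworth",
                                  "cheby1", "cheby2", "elliptic")
  if (uses_band) {
    stopifnot(inherits(band, "band_spec"))
    if (band$f_high >= fs / 2) {
      stop(sprintf("band infeasible: f_high = %g Hz must be below fs/2 = %g Hz",
                   band$f_high, fs / 2), call. = FALSE)
    }
  }
  out <- switch(
    spec$family,
    butterworth = list(
      kind = "linear_iir",
      sos = design_iir_bandpass(butter_prototype(spec$order_param), fs, band),
      effective_order = 2L * spec$order_param
    ),
    cheby1 = list(
      kind = "linear_iir",
      sos = design_iir_bandpass(
        cheby1_prototype(spec$order_param, spec$passband_ripple_db), fs, band),
      effective_order = 2L * spec$order_param
    ),
    cheby2 = list(
      kind = "linear_iir",
      sos = design_iir_bandpass(
        cheby2_prototype(spec$order_param, spec$stopband_atten_db), fs, band),
      effective_order = 2L * spec$order_param
    ),
    elliptic = list(
      kind = "linear_iir",
      sos = design_iir_bandpass(
        elliptic_prototype(spec$order_param, spec$passband_ripple_db,
                           spec$stopband_atten_db), fs, band),
      effective_order = 2L * spec$order_param
    ),
    fir_hamming = {
      m <- round(spec$order_param * fs)
      taps <- as.numeric(signal::fir1(m, c(band$f_low, band$f_high) / (fs / 2),
                                      type = "pass"))
      list(kind = "linear_fir", taps = taps, effective_order = m)
    },
    fir_ls = {
      m <- round(spec$order_param * fs)
      lo_stop <- band$f_low - 0.2
      if (lo_stop <= 0) {
        lo_stop <- band$f_low / 2
        warning(sprintf("fir_ls lower stopband edge clamped to %g Hz", lo_stop),
                call. = FALSE)
      }
      taps <- firls_bandpass(m, fs, lo_stop, band$f_low, band$f_high,
                             band$f_high + 2)
      list(kind = "linear_fir", taps = taps, effective_order = m)
    },
    moving_average = list(
      kind = "procedural", method = "moving_average",
      window = odd_window(spec$order_param, fs), effective_order = NA_integer_
    ),
    median = list(
      kind = "procedural", method = "median",
      window = odd_window(spec$order_param, fs), effective_order = NA_integer_
    ),
    wavelet = list(
      kind = "procedural", method = "wavelet",
      level = as.integer(spec$order_param), effective_order = NA_integer_
    )
  )
  out$spec <- spec
  out$fs <- as.numeric(fs)
  out$band <- if (uses_band) band else NULL
  class(out) <- "ppg_filter"
  out
}

#' @export
print.ppg_filter <- function(x, ...) {
  desc <- switch(x$kind,
    linear_iir = sprintf("%d second-order sections", nrow(x$sos)),
    linear_fir = sprintf("%d taps", length(x$taps)),
    procedural = switch(x$method,
      moving_average = sprintf("moving average, window %d", x$window),
      median = sprintf("median, window %d", x$window),
      wavelet = sprintf("MODWT db2 denoiser, level %d", x$level))
  )
  cat(sprintf("<ppg_filter> %s order %g @ %g Hz: %s\n",
              x$spec$family, x$spec$order_param, x$fs, desc))
  invisible(x)
}

#' The recommended filter: 4th-order Chebyshev II bandpass
#'
#' Convenience wrapper returning `design_filter(filter_spec("cheby2", 4), ...)`
#' (20 dB stopband attenuation), the configuration the benchmark identifies
#' as the best quality-improving filter for short PPG records.
#'
#' @inheritParams design_filter
#' @return A `ppg_filter`, as from [design_filter()].
#' @export
optimal_filter <- function(fs, band = band_spec(0.5, 8)) {
  design_filter(filter_spec("cheby2", 4), fs = fs, band = band)
}

#' Magnitude response of a linear filter design
#'
#' Single-pass magnitude response (the zero-phase application squares this).
#'
#' @param f A `ppg_filter` of kind `linear_iir` or `linear_fir`.
#' @param freqs_hz Frequencies at which to evaluate, in Hz.
#' @return Numeric vector of |H(f)|.
#' @export
filter_magnitude <- function(f, freqs_hz) {
  stopifnot(inherits(f, "ppg_filter"))
  z <- exp(2i * pi * freqs_hz / f$fs)
  if (f$kind == "linear_iir") {
    h <- rep(1 + 0i, length(z))
    for (i in seq_len(nrow(f$sos))) {
      s <- f$sos[i, ]
      h <- h * (s[[1]] + s[[2]] / z + s[[3]] / z^2) /
        (1 + s[[5]] / z + s[[6]] / z^2)
    }
    unname(Mod(h))
  } else if (f$kind == "linear_fir") {
    k <- seq_along(f$taps) - 1L
    Mod(vapply(z, function(zz) sum(f$taps * zz^(-k)), complex(1)))
  } else {
    stop("magnitude response is only defined for linear designs", call. = FALSE)
  }
}
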