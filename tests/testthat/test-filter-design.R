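test_that("the bank enumerates 9 families x 10 ascending orders, no duplicates", {
  bank <- enumerate_bank()
  expect_length(bank, 90L)
  fam <- vapply(bank, function(s) s$family, character(1))
  ord <- vapply(bank, function(s) s$order_param, numeric(1))
  expect_length(unique(fam), 9L)
  expect_true(all(table(fam) == 10L))
  expect_false(anyDuplicated(paste(fam, ord)) > 0)
  for (f in unique(fam)) {
    expect_false(is.unsorted(ord[fam == f], strictly = TRUE))
  }
  expect_identical(enumerate_bank(), bank) # deterministic
  expect_length(enumerate_bank("cheby2"), 10L)
})

test_that("off-grid orders are rejected unless explicitly allowed", {
  expect_error(filter_spec("cheby2", 5), "off the cheby2 grid")
  s <- filter_spec("cheby2", 5, check_grid = FALSE)
  expect_equal(s$order_param, 5)
  expect_equal(s$stopband_atten_db, 20)
  expect_equal(filter_spec("elliptic", 4)$passband_ripple_db, 0.1)
  expect_equal(filter_spec("elliptic", 4)$stopband_atten_db, 30)
})

test_that("all IIR designs over the full grid are stable SOS cascades", {
  band <- band_spec(0.5, 8)
  for (fam in c("butterworth", "cheby1", "cheby2", "elliptic")) {
    for (ord in seq(2, 20, by = 2)) {
      f <- design_filter(filter_spec(fam, ord), fs = 1000, band = band)
      expect_identical(f$kind, "linear_iir")
      expect_equal(nrow(f$sos), ord) # design order n -> effective order 2n
      moduli <- apply(f$sos, 1L, function(s) max(Mod(polyroot(rev(s[4:6])))))
      expect_true(all(moduli < 1),
                  label = sprintf("%s order %d stable", fam, ord))
    }
  }
})

test_that("cheby2 order 4 has a flat band center and a 20 dB stopband floor", {
  f <- design_filter(filter_spec("cheby2", 4), fs = 1000, band_spec(0.5, 8))
  ctr <- sqrt(0.5 * 8)
  expect_lt(abs(20 * log10(filter_magnitude(f, ctr))), 0.1)
  # the band edges are the stopband edges of this design: exactly Rs down
  edge_db <- -20 * log10(filter_magnitude(f, c(0.5, 8)))
  expect_true(all(edge_db >= 20 - 1e-6))
  # equiripple floor everywhere outside the band
  out_db <- -20 * log10(filter_magnitude(f, c(0.05, 0.2, 20, 50, 100, 499)))
  expect_true(all(out_db >= 20 - 1e-6))
})

test_that("stated magnitude responses match time-domain tone measurements", {
  # independent route: push long pure tones through the zero-phase filter and
  # measure the steady-state RMS gain, which must equal |H(f)|^2
  fs <- 1000
  t <- (0:19999) / fs
  for (fam in c("butterworth", "cheby2")) {
    f <- design_filter(filter_spec(fam, 6), fs = fs, band_spec(0.5, 8))
    for (freq in c(2, 5, 12)) {
      x <- sin(2 * pi * freq * t)
      y <- apply_zero_phase(f, ppg_record(x, fs))$samples
      core <- 5000:15000 # steady-state interior
      gain <- sqrt(mean(y[core]^2) / mean(x[core]^2))
      expect_equal(gain, filter_magnitude(f, freq)^2, tolerance = 2e-2,
                   label = sprintf("%s gain at %g Hz", fam, freq))
    }
  }
})

test_that("window lengths in seconds convert to odd sample counts", {
  f <- design_filter(filter_spec("moving_average", 0.05), fs = 1000)
  expect_identical(f$window, 51L) # 50 samples forced odd
  expect_identical(design_filter(filter_spec("median", 0.25), fs = 1000)$window,
                   251L)
  # odd product stays as-is
  f2 <- design_filter(filter_spec("moving_average", 0.05, check_grid = FALSE),
                      fs = 900) # 45 samples
  expect_identical(f2$window, 45L)
})

test_that("hamming FIR designs are symmetric with unit passband-center gain", {
  f <- design_filter(filter_spec("fir_hamming", 0.05), fs = 1000,
                     band_spec(0.5, 8))
  expect_length(f$taps, 51L) # round(0.05 * 1000) + 1
  expect_equal(f$taps, rev(f$taps), tolerance = 1e-14)
  expect_equal(filter_magnitude(f, (0.5 + 8) / 2), 1, tolerance = 1e-9)
  f2 <- design_filter(filter_spec("fir_hamming", 0.50), fs = 1000)
  expect_length(f2$taps, 501L)
  expect_equal(f2$taps, rev(f2$taps), tolerance = 1e-14)
})

test_that("least-squares FIR matches a dense-grid numerical LS oracle", {
  fs <- 1000
  f <- design_filter(filter_spec("fir_ls", 0.10), fs = fs, band_spec(0.5, 8))
  expect_length(f$taps, 101L)
  expect_equal(f$taps, rev(f$taps), tolerance = 1e-12)
  # oracle: discretize the integrated squared error on an equally spaced
  # frequency grid (so each band is weighted by its width) and solve the
  # regression A(w) = sum c_k cos(k w) ~ D(w) over the defined bands
  M <- 50L
  grid <- function(a, b) seq(a, b, by = 0.02)
  fr <- c(grid(0, 0.3), grid(0.5, 8), grid(10, 500))
  w <- pi * fr / (fs / 2)
  d <- as.numeric(fr >= 0.5 & fr <= 8)
  X <- outer(w, 0:M, function(wi, k) cos(k * wi))
  cvec <- qr.solve(X, d)
  h_oracle <- c(rev(cvec[-1]) / 2, cvec[1], cvec[-1] / 2)
  # agreement limited by the oracle's grid discretization of the integrals
  expect_lt(max(abs(f$taps - h_oracle)), 5e-4)
  # behavioral check: passband roughly unity (LS designs ripple near the
  # narrow transitions), stopbands strongly attenuated
  f3 <- design_filter(filter_spec("fir_ls", 0.30), fs = fs, band_spec(0.5, 8))
  expect_true(all(abs(filter_magnitude(f3, c(2, 3, 5)) - 1) < 0.15))
  expect_true(all(filter_magnitude(f3, c(30, 50, 100)) < 0.05))
})

test_that("fir_ls clamps a non-positive lower stopband edge with a warning", {
  expect_warning(
    f <- design_filter(filter_spec("fir_ls", 0.10), fs = 1000,
                       band = band_spec(0.15, 8)),
    "clamped"
  )
  expect_length(f$taps, 101L)
})

test_that("infeasible bands are rejected at design time", {
  expect_error(design_filter(filter_spec("butterworth", 4), fs = 15,
                             band = band_spec(0.5, 8)), "infeasible")
  expect_error(band_spec(8, 0.5))
  expect_error(band_spec(0, 8))
})

test_that("the recommended filter is the 4th-order Chebyshev II", {
  f <- optimal_filter(1000, band_spec(0.5, 8))
  expect_identical(f$spec$family, "cheby2")
  expect_equal(f$spec$order_param, 4)
  expect_equal(f$spec$stopband_atten_db, 20)
  ref <- design_filter(filter_spec("cheby2", 4), fs = 1000, band_spec(0.5, 8))
  expect_identical(f$sos, ref$sos)
})
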