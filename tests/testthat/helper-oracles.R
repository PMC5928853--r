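# Independent brute-force oracles used across the suite.

# third standardized moment by explicit summation (population sd)
brute_skewness <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sd_pop <- sqrt(sum((x - mu)^2) / n)
  sum(((x - mu) / sd_pop)^3) / n
}

# centered moving average with truncated windows, naive double loop
brute_moving_average <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) mean(x[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}

# centered sliding median with truncated windows, naive sort per position
brute_median_filter <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- sort(x[max(1L, i - h):min(n, i + h)])
    m <- length(w)
    if (m %% 2L) w[(m + 1L) %/% 2L] else (w[m %/% 2L] + w[m %/% 2L + 1L]) / 2
  }, numeric(1))
}

# time-domain circular MODWT with the db2 wavelet, from the published
# orthonormal filter coefficients (independent of the package's FFT path)
naive_modwt_db2 <- function(x, J) {
  h <- c(0.4829629131445341, 0.8365163037378079,
         0.2241438680420134, -0.1294095225512604) / sqrt(2)
  g <- rev(h) * c(1, -1, 1, -1)
  N <- length(x)
  V <- x
  W <- vector("list", J)
  for (j in seq_len(J)) {
    dil <- 2^(j - 1L)
    Wj <- numeric(N)
    Vj <- numeric(N)
    for (t in seq_len(N)) {
      idx <- ((t - 1L) - dil * (0:3)) %% N + 1L
      Wj[t] <- sum(g * V[idx])
      Vj[t] <- sum(h * V[idx])
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V)
}

# small labeled synthetic cohort, cached per test run
test_cohort <- local({
  cache <- NULL
  function(n = 5L) {
    if (is.null(cache)) {
      cache <<- unlist(lapply(c("G1", "G2", "G3"), function(g) {
        lapply(seq_len(n), function(i) {
          synth_ppg_record(g, seed = 100 * match(g, c("G1", "G2", "G3")) + i,
                           subject_id = sprintf("%s_%02d", g, i))
        })
      }), recursive = FALSE)
    }
    cache
  }
})
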