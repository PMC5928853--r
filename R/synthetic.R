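# Synthetic PPG generator: a two-Gaussian beat template (systolic wave plus
# smaller, later diastolic/dicrotic wave) repeated at a jittered heart rate,
# with additive noise scaled by quality-grade presets, digitised to a 12-bit
# range.

# run expr with a private RNG state seeded by `seed` (NULL = use current)
with_record_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

#' Default beat morphology parameters
#'
#' Two-Gaussian template per beat: a systolic wave (amplitude 1, centered at
#' 0.3 of the beat period, width 0.10 of the period) and a diastolic wave
#' (amplitude 0.4, center 0.62, width 0.14). Centers/widths are fractions of
#' the (jittered) beat period; amplitudes are in template units that
#' `amplitude_scale` maps onto the 12-bit output range around `dc_offset`.
#'
#' @return Named list of beat-model parameters.
#' @export
default_beat_model <- function() {
  list(
    heart_rate = 73,      # beats/min, population mean at rest
    heart_rate_sd = 10,   # between-record spread, beats/min
    jitter_sd = 0.03,     # per-beat multiplicative period jitter
    systolic = c(amplitude = 1.0, center = 0.30, width = 0.10),
    diastolic = c(amplitude = 0.4, center = 0.62, width = 0.14),
    amplitude_scale = 1300,
    dc_offset = 1800
  )
}

#' Per-grade noise presets
#'
#' Noise amplitudes are in beat-template units (systolic amplitude = 1).
#' G1 ("excellent") carries negligible noise; G2 ("acceptable") moderate
#' baseline wander and broadband noise that obscures the diastolic wave but
#' not the heartbeat; G3 ("unfit") noise whose combined amplitude exceeds
#' the beat train, drowning the heartbeat period. These presets are
#' calibrated fixtures for testing, not physiological claims.
#'
#' @return Named list (`G1`, `G2`, `G3`) of noise-model parameter lists:
#'   `baseline` (amplitude, frequency Hz), `white_sd`, `powerline`
#'   (amplitude, frequency Hz), `burst` (probability per record, amplitude,
#'   duration s).
#' @export
grade_noise_presets <- function() {
  list(
    G1 = list(baseline = c(amplitude = 0.02, frequency = 0.25),
              white_sd = 0.01,
              powerline = c(amplitude = 0.005, frequency = 50),
              burst = c(probability = 0, amplitude = 0, duration = 0.3)),
    G2 = list(baseline = c(amplitude = 0.35, frequency = 0.30),
              white_sd = 0.10,
              powerline = c(amplitude = 0.05, frequency = 50),
              burst = c(probability = 0.3, amplitude = 0.4, duration = 0.3)),
    G3 = list(baseline = c(amplitude = 1.2, frequency = 0.35),
              white_sd = 0.60,
              powerline = c(amplitude = 0.3, frequency = 50),
              burst = c(probability = 0.9, amplitude = 1.5, duration = 0.6))
  )
}

#' Generate one synthetic PPG record
#'
#' @param grade Quality grade `"G1"`, `"G2"` or `"G3"`; selects the noise
#'   preset and becomes the record label.
#' @param duration_s Record length in seconds (default 2.1).
#' @param fs Sampling rate in Hz (default 1000).
#' @param seed Integer seed; the record is a deterministic function of
#'   (grade, duration, fs, seed, models). `NULL` draws from the session RNG.
#' @param heart_rate Fixed heart rate in beats/min; `NULL` (default) draws
#'   one per record from N(73, 10) truncated to \[40, 120\].
#' @param beat Beat-model list, see [default_beat_model()].
#' @param noise Noise-model list overriding the grade preset (same shape as
#'   one element of [grade_noise_presets()]).
#' @param subject_id,segment_id Identifiers for the record.
#' @return A labeled [ppg_record()] with samples rounded and clipped to the
#'   12-bit range 0--4095.
#' @examples
#' r <- synth_ppg_record("G1", seed = 1)
#' windowed_sqi(r)$record_sqi
#' @export
synth_ppg_record <- function(grade, duration_s = 2.1, fs = 1000, seed = NULL,
                             heart_rate = NULL, beat = default_beat_model(),
                             noise = NULL, subject_id = "s000",
                             segment_id = "seg1") {
  grade <- match.arg(grade, c("G1", "G2", "G3"))
  if (duration_s < 1.0) {
    stop("'duration_s' must be at least 1 s (one SQI window)", call. = FALSE)
  }
  if (is.null(noise)) noise <- grade_noise_presets()[[grade]]
  hi_freq <- max(noise$baseline["frequency"], noise$powerline["frequency"])
  if (fs <= 2 * hi_freq) {
    stop("fs must exceed twice the highest noise frequency", call. = FALSE)
  }
  with_record_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1L) / fs
    hr <- if (is.null(heart_rate)) {
      min(max(stats::rnorm(1, beat$heart_rate, beat$heart_rate_sd), 40), 120)
    } else {
      heart_rate
    }
    period <- 60 / hr
    # beat onsets: random phase, per-beat multiplicative period jitter
    onset <- -stats::runif(1) * period
    sig <- numeric(n)
    while (onset < duration_s + period) {
      p <- period * (1 + if (beat$jitter_sd > 0) {
        stats::rnorm(1, 0, beat$jitter_sd)
      } else 0)
      for (wave in list(beat$systolic, beat$diastolic)) {
        ctr <- onset + wave["center"] * p
        sig <- sig + wave["amplitude"] *
          exp(-(t - ctr)^2 / (2 * (wave["width"] * p)^2))
      }
      onset <- onset + p
    }
    nz <- noise$baseline["amplitude"] *
      sin(2 * pi * noise$baseline["frequency"] * t + stats::runif(1, 0, 2 * pi))
    nz <- nz + noise$powerline["amplitude"] *
      sin(2 * pi * noise$powerline["frequency"] * t + stats::runif(1, 0, 2 * pi))
    if (noise$white_sd > 0) nz <- nz + stats::rnorm(n, 0, noise$white_sd)
    if (noise$burst["probability"] > 0 &&
        stats::runif(1) < noise$burst["probability"]) {
      ctr <- stats::runif(1, 0, duration_s)
      env <- exp(-(t - ctr)^2 / (2 * (noise$burst["duration"] / 2)^2))
      fm <- stats::runif(1, 5, 15) # motion-artifact oscillation, Hz
      nz <- nz + noise$burst["amplitude"] * env *
        sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi))
    }
    counts <- beat$dc_offset + beat$amplitude_scale * (sig + nz)
    counts <- pmin(pmax(round(counts), 0), 4095) # 12-bit AD
    ppg_record(counts, fs = fs, subject_id = subject_id,
               segment_id = segment_id, label = grade)
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_per_group` records per grade (default 36/132/51, the group
#' sizes of the study dataset) plus a manifest, via [write_ppg_records()].
#' Per-record seeds are derived deterministically from `seed`, so the same
#' master seed reproduces byte-identical files.
#'
#' @param n_per_group Integer vector of length 3: counts for G1, G2, G3.
#' @param seed Master seed (integer).
#' @param out_dir Output directory.
#' @param duration_s,fs Record geometry, as in [synth_ppg_record()].
#' @return The manifest path.
#' @export
synth_ppg_dataset <- function(n_per_group = c(G1 = 36, G2 = 132, G3 = 51),
                              seed = 1L, out_dir, duration_s = 2.1,
                              fs = 1000) {
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 0))
  grades <- rep(c("G1", "G2", "G3"), times = n_per_group)
  records <- lapply(seq_along(grades), function(i) {
    synth_ppg_record(
      grades[i], duration_s = duration_s, fs = fs,
      seed = derive_seed(seed, i),
      subject_id = sprintf("s%03d", i), segment_id = "seg1"
    )
  })
  write_ppg_records(records, out_dir)
}

# deterministic 31-bit per-record seed stream
derive_seed <- function(master, i) {
  (as.numeric(master) %% 65536 * 9973 + i * 7919) %% 2147483647 + 1
}
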