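#' Default run configuration
#'
#' All knobs of a benchmarking run in one validated list: sampling rate,
#' passband, SQI window, IIR design constants, the order grids, and the
#' synthetic-generator models.
#'
#' @return Nested list; see fields in the returned object.
#' @export
default_run_config <- function() {
  list(
    fs = 1000,
    band = list(f_low = 0.5, f_high = 8),
    window_len_s = 1.0,
    duration_s = 2.1,
    design = list(
      passband_ripple_db = 0.1,
      cheby2_stopband_db = 20,
      elliptic_stopband_db = 30
    ),
    grids = family_grids(),
    generator = list(
      beat = default_beat_model(),
      presets = grade_noise_presets(),
      n_per_group = c(G1 = 36, G2 = 132, G3 = 51)
    ),
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file and merges it (recursively) over
#' [default_run_config()]; unknown top-level keys are rejected and the
#' merged configuration is validated.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg <- utils::modifyList(cfg, user)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(fs) || fs <= 0) stop("config: fs must be > 0", call. = FALSE)
    if (!is.numeric(band$f_low) || !is.numeric(band$f_high) ||
        band$f_low <= 0 || band$f_high <= band$f_low ||
        band$f_high >= fs / 2) {
      stop("config: band must satisfy 0 < f_low < f_high < fs/2", call. = FALSE)
    }
    if (!is.numeric(window_len_s) || window_len_s <= 0) {
      stop("config: window_len_s must be > 0", call. = FALSE)
    }
    if (!is.numeric(duration_s) || duration_s < window_len_s) {
      stop("config: duration_s must cover at least one window", call. = FALSE)
    }
    if (any(vapply(design, Negate(is.numeric), logical(1)))) {
      stop("config: design constants must be numeric", call. = FALSE)
    }
  })
  cfg
}

config_band <- function(cfg) band_spec(cfg$band$f_low, cfg$band$f_high)
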