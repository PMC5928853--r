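#' Construct a PPG record
#'
#' A `ppg_record` holds one sampled photoplethysmogram segment together with
#' its sampling rate, identity, and (optionally) an expert quality label.
#' Amplitudes are in arbitrary units; records digitised with a 12-bit
#' converter nominally span 0--4095, but no clipping is applied here.
#'
#' @param samples Numeric vector of amplitude samples. Must be non-empty and
#'   finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param subject_id,segment_id Character identifiers.
#' @param label Quality grade: one of `"G1"` (excellent), `"G2"` (acceptable),
#'   `"G3"` (unfit), or `"unlabeled"`.
#' @return An object of class `ppg_record` with fields `samples`, `fs`,
#'   `subject_id`, `segment_id`, `label`.
#' @examples
#' r <- ppg_record(sin(2 * pi * 1.2 * seq(0, 2.1, by = 1e-3)), fs = 1000)
#' ppg_duration(r)
#' @export
ppg_record <- function(samples, fs, subject_id = "s000", segment_id = "seg1",
                       label = "unlabeled") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("'samples' must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("'samples' must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a positive finite scalar (Hz)", call. = FALSE)
  }
  label <- match.arg(label, c("unlabeled", "G1", "G2", "G3"))
  structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      subject_id = as.character(subject_id),
      segment_id = as.character(segment_id),
      label = label
    ),
    class = "ppg_record"
  )
}

#' @rdname ppg_record
#' @param x A `ppg_record`.
#' @export
ppg_duration <- function(x) {
  stopifnot(inherits(x, "ppg_record"))
  length(x$samples) / x$fs
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf(
    "<ppg_record> %s/%s: %d samples @ %g Hz (%.3f s), label %s\n",
    x$subject_id, x$segment_id, length(x$samples), x$fs,
    ppg_duration(x), x$label
  ))
  invisible(x)
}

manifest_header <- c("subject_id", "segment_id", "file", "fs", "label")

#' Read PPG records from a manifest
#'
#' The on-disk format is one plain-text sample file per record (ASCII numeric
#' tokens separated by whitespace or newlines) plus a manifest CSV with header
#' `subject_id,segment_id,file,fs,label`. An empty label cell yields
#' `"unlabeled"`.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param data_dir Directory the manifest's `file` column is relative to.
#'   Defaults to the manifest's own directory.
#' @return A list of [ppg_record()] objects, in manifest row order.
#' @seealso [write_ppg_records()]
#' @export
read_ppg_records <- function(manifest_path, data_dir = dirname(manifest_path)) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- utils::read.csv(manifest_path, colClasses = "character",
                         check.names = FALSE)
  if (!identical(names(man), manifest_header)) {
    stop("manifest header must be exactly '",
         paste(manifest_header, collapse = ","), "'", call. = FALSE)
  }
  if (nrow(man) == 0L) {
    return(list())
  }
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    path <- file.path(data_dir, row$file)
    if (!file.exists(path)) {
      stop(sprintf("manifest row %d (%s/%s): sample file not found: %s",
                   i, row$subject_id, row$segment_id, path), call. = FALSE)
    }
    fs <- suppressWarnings(as.numeric(row$fs))
    if (is.na(fs) || fs <= 0) {
      stop(sprintf("manifest row %d: fs must be a positive number, got '%s'",
                   i, row$fs), call. = FALSE)
    }
    tokens <- scan(path, what = character(), quiet = TRUE)
    vals <- suppressWarnings(as.numeric(tokens))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop(sprintf("non-numeric token '%s' at position %d in %s",
                   tokens[bad], bad, path), call. = FALSE)
    }
    label <- if (is.na(row$label) || !nzchar(row$label)) "unlabeled" else row$label
    ppg_record(vals, fs = fs, subject_id = row$subject_id,
               segment_id = row$segment_id, label = label)
  })
}

#' Write PPG records and a manifest
#'
#' Writes one sample file per record (one value per line, 17 significant
#' digits so a read/write round trip is lossless) and a manifest CSV.
#'
#' @param records List of [ppg_record()] objects.
#' @param out_dir Output directory; created if needed.
#' @param manifest_name File name for the manifest CSV.
#' @return The manifest path, invisibly usable as input to
#'   [read_ppg_records()].
#' @export
write_ppg_records <- function(records, out_dir, manifest_name = "manifest.csv") {
  stopifnot(is.list(records))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r, "ppg_record"))
    fname <- sprintf("%s_%s.txt", r$subject_id, r$segment_id)
    writeLines(sprintf("%.17g", r$samples), file.path(out_dir, fname))
    data.frame(subject_id = r$subject_id, segment_id = r$segment_id,
               file = fname, fs = r$fs,
               label = if (identical(r$label, "unlabeled")) "" else r$label,
               stringsAsFactors = FALSE)
  })
  man <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    as.data.frame(stats::setNames(rep(list(character()), 5), manifest_header))
  }
  manifest_path <- file.path(out_dir, manifest_name)
  utils::write.table(man, manifest_path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  manifest_path
}
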