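#' Benchmark a filter bank on labeled PPG records
#'
#' Every record is filtered zero-phase with every configuration in `bank`
#' and scored with [windowed_sqi()]; the grid cell for
#' (family, order, group) is the arithmetic mean of the record-level SQIs
#' over that quality group. The same mean on the unfiltered records gives
#' the raw per-group baseline. The whole computation is deterministic given
#' its inputs.
#'
#' @param records List of labeled [ppg_record()]s (labels G1/G2/G3), all at
#'   the same sampling rate.
#' @param bank List of [filter_spec()]s; defaults to the full 90-configuration
#'   bank from [enumerate_bank()].
#' @param band Passband for the frequency-selective families.
#' @param window_len_s SQI window length in seconds.
#' @return An object of class `ppg_benchmark`: list with `raw_group_sqi`
#'   (named numeric), `grid` (data frame `family, order_param, group,
#'   mean_sqi`), `band`, `fs`, `window_len_s`, `n_records` (per group);
#'   `norm_grid` and `ranking` are filled by [normalize_scores()] and
#'   [rank_configurations()].
#' @export
run_benchmark <- function(records, bank = enumerate_bank(),
                          band = band_spec(0.5, 8), window_len_s = 1.0) {
  if (length(records) == 0L) stop("no records supplied", call. = FALSE)
  if (length(bank) == 0L) stop("empty filter bank", call. = FALSE)
  labs <- vapply(records, function(r) r$label, character(1))
  if (any(labs == "unlabeled")) {
    ids <- vapply(records[labs == "unlabeled"],
                  function(r) paste0(r$subject_id, "/", r$segment_id),
                  character(1))
    stop("unlabeled records: ", paste(ids, collapse = ", "), call. = FALSE)
  }
  fs <- unique(vapply(records, function(r) r$fs, numeric(1)))
  if (length(fs) != 1L) {
    stop("all records must share one sampling rate; got ",
         paste(fs, collapse = ", "), call. = FALSE)
  }
  groups <- sort(unique(labs))
  raw_sqi <- vapply(records, function(r) {
    windowed_sqi(r, window_len_s)$record_sqi
  }, numeric(1))
  raw_group_sqi <- vapply(groups, function(g) mean(raw_sqi[labs == g]),
                          numeric(1))

  cells <- vector("list", length(bank))
  for (i in seq_along(bank)) {
    spec <- bank[[i]]
    f <- design_filter(spec, fs = fs, band = band)
    sqi <- vapply(records, function(r) {
      windowed_sqi(apply_zero_phase(f, r), window_len_s)$record_sqi
    }, numeric(1))
    cells[[i]] <- data.frame(
      family = spec$family, order_param = spec$order_param, group = groups,
      mean_sqi = vapply(groups, function(g) mean(sqi[labs == g]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  structure(
    list(raw_group_sqi = raw_group_sqi,
         grid = do.call(rbind, cells),
         norm_grid = NULL, ranking = NULL,
         band = band, fs = fs, window_len_s = window_len_s,
         n_records = vapply(groups, function(g) sum(labs == g), integer(1))),
    class = "ppg_benchmark"
  )
}

#' Min-max normalize benchmark scores per quality group
#'
#' Within each group, the mean SQIs of all configurations are mapped to
#' \[0, 1\] by `(x - min) / (max - min)`; a degenerate all-equal group maps
#' to 0. Raw (unfiltered) baselines are not part of the normalization
#' domain.
#'
#' @param result A `ppg_benchmark` from [run_benchmark()].
#' @return The benchmark with `norm_grid` filled (grid plus a `norm_sqi`
#'   column).
#' @export
normalize_scores <- function(result) {
  stopifnot(inherits(result, "ppg_benchmark"))
  g <- result$grid
  if (is.null(g) || nrow(g) == 0L) stop("benchmark grid is empty", call. = FALSE)
  g$norm_sqi <- NA_real_
  for (grp in unique(g$group)) {
    sel <- g$group == grp
    v <- g$mean_sqi[sel]
    rng <- range(v)
    g$norm_sqi[sel] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
  }
  result$norm_grid <- g
  result
}

#' Rank filter configurations by combined normalized score
#'
#' The combined score of a configuration is the sum over quality groups of
#' its normalized mean SQI (the height of its stacked bar). Configurations
#' are ordered by descending score; ties break toward the lower order
#' parameter (lower orders are preferable in practice), then by family name.
#'
#' @param result A `ppg_benchmark`; [normalize_scores()] is applied first if
#'   needed.
#' @return The benchmark with `ranking` filled: a data frame
#'   `family, order_param, combined_score, rank`.
#' @export
rank_configurations <- function(result) {
  stopifnot(inherits(result, "ppg_benchmark"))
  if (is.null(result$norm_grid)) result <- normalize_scores(result)
  ng <- result$norm_grid
  agg <- stats::aggregate(norm_sqi ~ family + order_param, data = ng, FUN = sum)
  names(agg)[names(agg) == "norm_sqi"] <- "combined_score"
  ord <- order(-agg$combined_score, agg$order_param, agg$family)
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  result$ranking <- agg
  result
}

#' Write a benchmark report
#'
#' Writes a CSV with one row per (configuration, group) — columns
#' `family, order_param, group, mean_sqi, norm_sqi, combined_score, rank` —
#' plus a plain-text summary naming the top-ranked configuration.
#'
#' @param result A `ppg_benchmark`; normalization and ranking are applied if
#'   missing.
#' @param out_csv Output CSV path.
#' @param summary_path Summary text path; defaults to the CSV path with a
#'   `_summary.txt` suffix.
#' @return `out_csv`, invisibly reusable.
#' @export
report_benchmark <- function(result, out_csv,
                             summary_path = sub("\\.csv$", "_summary.txt",
                                                out_csv)) {
  stopifnot(inherits(result, "ppg_benchmark"))
  if (is.null(result$grid) || nrow(result$grid) == 0L) {
    stop("benchmark grid is empty; nothing to report", call. = FALSE)
  }
  result <- rank_configurations(result)
  tab <- merge(result$norm_grid, result$ranking,
               by = c("family", "order_param"), sort = FALSE)
  tab <- tab[order(tab$rank, tab$group),
             c("family", "order_param", "group", "mean_sqi", "norm_sqi",
               "combined_score", "rank")]
  dir.create(dirname(out_csv), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   out_csv, row.names = FALSE, quote = FALSE)
  top <- result$ranking[1L, ]
  raw <- paste(sprintf("%s=%.4f", names(result$raw_group_sqi),
                       result$raw_group_sqi), collapse = ", ")
  writeLines(c(
    sprintf("Top configuration: %s, order %g (combined normalized SQI %.4f)",
            top$family, top$order_param, top$combined_score),
    sprintf("Band: %g-%g Hz at fs = %g Hz; SQI window %g s",
            result$band$f_low, result$band$f_high, result$fs,
            result$window_len_s),
    sprintf("Raw mean record SQI: %s", raw),
    sprintf("Records per group: %s",
            paste(sprintf("%s=%d", names(result$n_records), result$n_records),
                  collapse = ", "))
  ), summary_path)
  invisible(out_csv)
}

#' @export
print.ppg_benchmark <- function(x, ...) {
  cat(sprintf("<ppg_benchmark> %d configurations x %d groups (%s records)\n",
              length(unique(paste(x$grid$family, x$grid$order_param))),
              length(x$raw_group_sqi), sum(x$n_records)))
  if (!is.null(x$ranking)) {
    top <- x$ranking[1L, ]
    cat(sprintf("  top: %s order %g, combined score %.4f\n",
                top$family, top$order_param, top$combined_score))
  }
  invisible(x)
}
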