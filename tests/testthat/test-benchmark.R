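# construct a minimal ppg_benchmark shell for the pure score operations
fake_benchmark <- function(grid) {
  structure(list(raw_group_sqi = c(G1 = 0), grid = grid, norm_grid = NULL,
                 ranking = NULL, band = band_spec(0.5, 8), fs = 1000,
                 window_len_s = 1,
                 n_records = c(G1 = 1L)),
            class = "ppg_benchmark")
}

test_that("a pass-through configuration reproduces the raw group SQIs", {
  records <- test_cohort()
  # 1-sample moving-average window: the identity filter
  passthrough <- list(filter_spec("moving_average", 4e-4, check_grid = FALSE))
  res <- run_benchmark(records, bank = passthrough)
  for (g in names(res$raw_group_sqi)) {
    expect_equal(res$grid$mean_sqi[res$grid$group == g],
                 res$raw_group_sqi[[g]], tolerance = 1e-12)
  }
})

test_that("grid cells equal hand-computed group means on a tiny cohort", {
  set.seed(51)
  mk <- function(x, id, lab) ppg_record(x, 4, id, "seg1", lab)
  # fs 4, window 1 s -> two 4-sample windows per 8-sample record
  recs <- list(mk(c(0, 0, 1, 0, 2, 1, 1, 1), "a", "G1"),
               mk(c(5, 1, 1, 1, 0, 1, 1, 4), "b", "G1"),
               mk(c(0, 1, 2, 3, 1, 1, 2, 1), "c", "G2"),
               mk(c(9, 9, 8, 9, 3, 1, 2, 2), "d", "G2"))
  bank <- list(filter_spec("moving_average", 0.75, check_grid = FALSE)) # 3-sample window
  res <- run_benchmark(recs, bank = bank, window_len_s = 1)
  expected <- vapply(split(recs, c("G1", "G1", "G2", "G2")), function(rs) {
    mean(vapply(rs, function(r) {
      sm <- brute_moving_average(r$samples, 3L)
      max(brute_skewness(sm[1:4]), brute_skewness(sm[5:8]))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(res$grid$mean_sqi[res$grid$group == "G1"], expected[["G1"]],
               tolerance = 1e-12)
  expect_equal(res$grid$mean_sqi[res$grid$group == "G2"], expected[["G2"]],
               tolerance = 1e-12)
})

test_that("min-max normalization maps each group onto [0, 1]", {
  grid <- data.frame(
    family = rep(c("a", "b"), each = 1), order_param = 1,
    group = c("G1", "G1"), mean_sqi = c(0.2, 0.7)
  )
  out <- normalize_scores(fake_benchmark(grid))$norm_grid
  expect_equal(out$norm_sqi, c(0, 1))
  # degenerate all-equal group maps to 0
  grid$mean_sqi <- c(0.4, 0.4)
  expect_equal(normalize_scores(fake_benchmark(grid))$norm_grid$norm_sqi,
               c(0, 0))
  # three-point case
  grid3 <- data.frame(family = c("a", "b", "c"), order_param = 1,
                      group = "G1", mean_sqi = c(1, 2, 4))
  expect_equal(normalize_scores(fake_benchmark(grid3))$norm_grid$norm_sqi,
               c(0, 1 / 3, 1))
})

test_that("ranking sums normalized scores and breaks ties toward low order", {
  grid <- expand.grid(family = c("x", "y"), order_param = c(4, 8),
                      group = c("G1", "G2", "G3"), stringsAsFactors = FALSE)
  grid$mean_sqi <- 0.5
  grid$mean_sqi[grid$family == "x" & grid$order_param == 4] <- 1 # max in all groups
  grid$mean_sqi[grid$family == "y" & grid$order_param == 8] <- 0 # min in all groups
  res <- rank_configurations(fake_benchmark(grid))
  rk <- res$ranking
  expect_identical(sort(rk$rank), 1:4) # a permutation
  expect_identical(rk$family[1], "x")
  expect_equal(rk$order_param[1], 4)
  expect_equal(rk$combined_score[1], 3.0)
  # the two tied middle configs (x,8) and (y,4): lower order wins
  tied <- rk[rk$combined_score > 0 & rk$combined_score < 3, ]
  expect_equal(tied$order_param[1], 4)
  expect_identical(tied$family[1], "y")
})

test_that("duplicating every record leaves group means unchanged", {
  records <- test_cohort()
  bank <- list(filter_spec("cheby2", 4), filter_spec("median", 0.1))
  r1 <- run_benchmark(records, bank = bank)
  r2 <- run_benchmark(c(records, records), bank = bank)
  expect_equal(r2$grid$mean_sqi, r1$grid$mean_sqi, tolerance = 1e-12)
  expect_equal(r2$raw_group_sqi, r1$raw_group_sqi, tolerance = 1e-12)
})

test_that("benchmark rejects unlabeled records, naming them", {
  recs <- c(test_cohort()[1:2],
            list(ppg_record(rnorm(2100), 1000, "sbad", "seg9")))
  expect_error(run_benchmark(recs), "sbad/seg9")
  expect_error(run_benchmark(list()), "no records")
  expect_error(run_benchmark(test_cohort(), bank = list()), "empty filter bank")
  mixed <- c(test_cohort()[1:2], list(synth_ppg_record("G1", fs = 500,
                                                       duration_s = 2.1,
                                                       seed = 1)))
  expect_error(run_benchmark(mixed), "sampling rate")
})

test_that("the report round-trips numerically and names the top configuration", {
  dir <- withr::local_tempdir()
  records <- test_cohort()
  bank <- enumerate_bank(c("cheby2", "moving_average"))
  res <- run_benchmark(records, bank = bank)
  csv <- file.path(dir, "report.csv")
  report_benchmark(res, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), length(bank) * 3L)
  expect_identical(names(tab), c("family", "order_param", "group", "mean_sqi",
                                 "norm_sqi", "combined_score", "rank"))
  ranked <- rank_configurations(res)$ranking
  got <- tab[tab$rank == 1L, ]
  expect_identical(unique(got$family), ranked$family[1])
  expect_equal(unique(got$combined_score), ranked$combined_score[1],
               tolerance = 1e-12)
  expect_equal(sort(unique(tab$rank)), seq_along(bank))
  # numeric round trip of the grid values
  key <- paste(tab$family, tab$order_param, tab$group)
  ref <- res$grid$mean_sqi[match(key, paste(res$grid$family,
                                            res$grid$order_param,
                                            res$grid$group))]
  expect_equal(tab$mean_sqi, ref, tolerance = 1e-12)
  summary_txt <- readLines(file.path(dir, "report_summary.txt"))
  expect_match(summary_txt[1], ranked$family[1])
  expect_error(report_benchmark(fake_benchmark(res$grid[0, ]), csv), "empty")
})

test_that("identical benchmark invocations give bit-identical reports", {
  dir <- withr::local_tempdir()
  records <- test_cohort()
  bank <- enumerate_bank(c("cheby2", "wavelet"))
  f1 <- file.path(dir, "a.csv")
  f2 <- file.path(dir, "b.csv")
  report_benchmark(run_benchmark(records, bank = bank), f1)
  report_benchmark(run_benchmark(records, bank = bank), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
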