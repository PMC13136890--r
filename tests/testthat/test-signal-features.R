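make_signal_df <- function(reads, positions, dwell = 2, mean = 0, sd = 0.1) {
  grid <- expand.grid(read_id = reads, position = positions,
                      stringsAsFactors = FALSE)
  data.frame(grid, dwell = dwell, mean = mean, sd = sd)
}

test_that("signal TSVs are read, validated and rejected with row numbers", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sig.tsv")
  sm0 <- signal_matrix(make_signal_df(c("r1", "r2"), 1:3), ref_length = 3)
  write_signal_tsv(sm0, path)
  sm <- read_signal_tsv(path, ref_length = 3)
  expect_s3_class(sm, "signal_matrix")
  expect_equal(nrow(sm), 6L)

  dup <- rbind(as.data.frame(sm0), as.data.frame(sm0)[1, ])
  expect_error(signal_matrix(dup), "duplicate")

  bad <- as.data.frame(sm0)
  bad$dwell[4] <- 0
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signal_tsv(path), "dwell.*4")

  utils::write.table(bad[, -3], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_signal_tsv(path), "missing columns")
})

test_that("coverage filter keeps reads at or above the fraction", {
  df <- rbind(make_signal_df("full", 1:120),
              make_signal_df("boundary", 13:120),   # 108/120 = 0.90
              make_signal_df("short", 21:120))      # 100/120
  sm <- signal_matrix(df, ref_length = 120)
  kept <- coverage_filter(sm, 0.9)
  expect_setequal(unique(kept$read_id), c("full", "boundary"))
  expect_equal(attr(kept, "reads_in"), 3L)
  expect_equal(attr(kept, "reads_out"), 2L)
  # min_frac 1 retains only full-coverage reads
  expect_equal(unique(coverage_filter(sm, 1)$read_id), "full")
  expect_error(coverage_filter(sm, 0), "min_frac")
})

test_that("robust scaling centers pooled data and honours the MAD constant", {
  # channel values {1..5} pooled across samples: median 3, raw MAD 1,
  # so 5 -> (5 - 3) / 1.4826
  mk <- function(vals, ids) {
    signal_matrix(data.frame(read_id = ids, position = 1,
                             dwell = exp(vals), mean = vals, sd = vals),
                  ref_length = 1)
  }
  pre <- preprocess_signals(mk(c(1, 2, 3), c("a", "b", "c")),
                            mk(c(4, 5), c("d", "e")))
  expect_equal(pre$control$mean[2], 2 / 1.4826, tolerance = 1e-12)
  expect_equal(pre$control$dwell[2], 2 / 1.4826, tolerance = 1e-12)
  pooled <- c(pre$modified$mean, pre$control$mean)
  expect_equal(median(pooled), 0)
  # order preserved per channel
  expect_equal(order(c(1, 2, 3, 4, 5)), order(pooled))
})

test_that("constant channels fall back to centering with a warning", {
  mk <- function(ids, mean) {
    signal_matrix(data.frame(read_id = ids, position = 1,
                             dwell = seq(1, 2, length.out = length(ids)),
                             mean = mean, sd = 0.1),
                  ref_length = 1)
  }
  expect_warning(
    pre <- preprocess_signals(mk(c("a", "b", "c"), 5), mk(c("d", "e"), 5)),
    "MAD")
  expect_equal(pre$modified$mean, rep(0, 3))
  expect_equal(pre$control$mean, rep(0, 2))
})

test_that("windowing assembles 9-vectors only from fully covered reads", {
  df <- rbind(make_signal_df("r1", 4:6, mean = 1:3),
              make_signal_df("r2", c(4, 6)))  # missing the center
  sm <- signal_matrix(df, ref_length = 10)
  w <- window_features(sm, 5)
  expect_true(w$defined)
  expect_equal(nrow(w$vectors), 1L)
  expect_equal(w$read_ids, "r1")
  expect_equal(ncol(w$vectors), 9L)
  # feature order: (log-dwell, mean, sd) at center-1, center, center+1
  expect_equal(unname(w$vectors[1, c("mean_m1", "mean_c0", "mean_p1")]),
               c(1, 2, 3))
  # r2 contributes nothing at centers 4, 5, 6
  for (ctr in 4:6) {
    expect_false("r2" %in% window_features(sm, ctr)$read_ids)
  }
  # edge centers are undefined
  expect_false(window_features(sm, 1)$defined)
  expect_false(window_features(sm, 10)$defined)
})

test_that("windowing never exceeds the minimum depth over the window", {
  sim <- simulate_dataset(tiny_sim_config(seed = 4))
  sm <- sim$signal$modified
  depth <- table(factor(sm$position, levels = 1:120))
  for (ctr in c(5L, 40L, 80L, 119L)) {
    w <- window_features(sm, ctr)
    expect_lte(nrow(w$vectors), min(depth[(ctr - 1):(ctr + 1)]))
  }
})

test_that("signal matrices round-trip through the TSV dialect", {
  sim <- simulate_dataset(tiny_sim_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signal_tsv(sim$signal$control, path)
  back <- read_signal_tsv(path, ref_length = 120)
  expect_equal(strip_attrs(back), strip_attrs(sim$signal$control),
               tolerance = 1e-12)
})
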