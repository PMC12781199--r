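test_that("truncate_downsample is the index-selection projection", {
  # waveform equal to its own 0-based sample index
  w <- 0:1399
  out <- truncate_downsample(w)
  expect_identical(out, seq(0L, 496L, by = 4L))
  expect_length(out, 125)
  expect_identical(truncate_downsample(rep(3.7, 1400)), rep(3.7, 125))
  expect_error(truncate_downsample(1:100), "1400")
  # list input gives the row-wise projection
  m <- truncate_downsample(list(w, w + 1))
  expect_equal(dim(m), c(2, 125))
  expect_equal(m[2, ], seq(1, 497, by = 4))
})

test_that("onset detection hits simulated onsets within a sampling step", {
  p <- default_nerve_profiles()$V.r
  set.seed(11)
  lats <- runif(30, 2.5, 9)
  for (lat in lats) {
    w <- synth_waveform(p, lat, 1500, 2)
    det <- detect_onset_and_first_peak(w)
    expect_lt(abs(det$onset_latency - lat), 0.05)
  }
})

test_that("mean detected onsets over many draws recover the profile means", {
  p <- default_nerve_profiles()
  set.seed(12)
  for (key in c("R.l", "V.r")) {
    prof <- p[[key]]
    det <- vapply(seq_len(800), function(i) {
      lat <- ionmqc:::draw_latency(prof)
      ionmqc:::detect_onset_one(synth_waveform(prof, lat, 1200, 2), 1, 5, 3L)[1]
    }, numeric(1))
    se <- sd(det) / sqrt(length(det))
    expect_lt(abs(mean(det) - prof$latency_mean), 3 * se + 0.01)
  }
})

test_that("operation context reproduces hand-computed channel means and time points", {
  rec <- dplyr::bind_rows(
    one_record("V1l", time = 1000), one_record("R1l", time = 2000),
    one_record("V1l", time = 4000), one_record("", time = 10000)
  )
  rec$amplitude <- c(100, 200, 300, 400)
  rec$recording_channel <- c(1L, 1L, 2L, 3L)
  ctx <- compute_operation_context(rec)
  expect_equal(ctx$ctx_ch_mean_1, 150)   # (100+200)/2
  expect_equal(ctx$ctx_ch_mean_2, 300)
  expect_equal(ctx$ctx_ch_mean_3, 400)
  expect_equal(ctx$ctx_ch_mean_4, 0)     # channel never used
  expect_equal(ctx$ctx_duration, 10000)
  # V1l occurred at 1000 and 4000 out of 10000
  expect_equal(ctx$ctx_tp_V1l_1, 0.1)
  expect_equal(ctx$ctx_tp_V1l_2, 0.4)
  expect_equal(ctx$ctx_tp_V1l_3, -1)     # padding sentinel
  # a label never used keeps all sentinel slots
  expect_equal(unlist(ctx[paste0("ctx_tp_S2r_", 1:4)]), rep(-1, 4),
               ignore_attr = TRUE)
  tp <- unlist(ctx[grep("^ctx_tp_", names(ctx))])
  expect_true(all(tp == -1 | (tp >= 0 & tp <= 1)))
  # median option and zero-duration error
  ctx_med <- compute_operation_context(rec, stat = "median")
  expect_equal(ctx_med$ctx_ch_mean_1, 150)
  rec0 <- one_record(time = 0)
  expect_error(compute_operation_context(rec0), "zero duration")
})

test_that("the default feature layout totals 216 and spans the documented blocks", {
  f <- small_features()
  expect_equal(ncol(f$x), 216)
  expect_equal(nrow(f$layout), 216)
  counts <- table(f$layout$block)
  expect_equal(unname(counts["emg_segment"]), 125, ignore_attr = TRUE)
  expect_equal(unname(counts["label_time_points"]), 48, ignore_attr = TRUE)
  expect_equal(unname(counts["extra_context"]), 27, ignore_attr = TRUE)
  # row count equals the filtered labelled-record count, nothing dropped
  expect_equal(nrow(f$x),
               nrow(filter_standard_labels(small_corpus()$records)))
})

test_that("switching blocks changes the width and warns outside 150-280", {
  corpus <- small_corpus()
  ctx <- compute_operation_context(corpus$records)
  lab <- filter_standard_labels(corpus$records)
  cfg <- feature_config(label_time_points = FALSE)
  f <- build_feature_matrix(lab, context = ctx, config = cfg,
                            normalize = FALSE)
  expect_equal(ncol(f$x), 216 - 48)
  cfg_wide <- feature_config(time_points_per_label = 8L)
  ctx8 <- compute_operation_context(corpus$records,
                                    time_points_per_label = 8L)
  f8 <- build_feature_matrix(lab, context = ctx8, config = cfg_wide,
                             normalize = FALSE)
  expect_equal(ncol(f8$x), 216 + 48)
  cfg_narrow <- feature_config(emg_segment = FALSE, label_time_points = FALSE)
  expect_warning(
    build_feature_matrix(lab, context = ctx, config = cfg_narrow,
                         normalize = FALSE),
    "150-280"
  )
})

test_that("one-hot targets are exact and decode back to the stored label", {
  f <- small_features()
  expect_true(all(rowSums(f$y$nerve) == 1))
  expect_true(all(rowSums(f$y$side) == 1))
  expect_true(all(rowSums(f$y$position) == 1))
  decoded <- join_label(
    c("V", "R", "S")[max.col(f$y$nerve)],
    c("l", "r")[max.col(f$y$side)],
    c("1", "2")[max.col(f$y$position)]
  )
  expect_identical(decoded, f$labels)
})

test_that("min-max normalization maps the fitted set into [0,1] and is frozen for reuse", {
  f <- small_features()
  rows_a <- seq_len(floor(nrow(f$x) / 2))
  rows_b <- setdiff(seq_len(nrow(f$x)), rows_a)
  norm_a <- fit_normalizer(f$x[rows_a, ], f$layout$feature)
  xa <- apply_normalizer(f$x[rows_a, ], norm_a)
  expect_gte(min(xa), 0)
  expect_lte(max(xa), 1)
  # refitting on other rows changes the parameters (so silent refits
  # on held-out data would be detectable); applying the frozen
  # normalizer never uses held-out statistics
  norm_b <- fit_normalizer(f$x[rows_b, ], f$layout$feature)
  expect_false(isTRUE(all.equal(norm_a$min, norm_b$min)))
  xb1 <- apply_normalizer(f$x[rows_b, ], norm_a)
  xb2 <- apply_normalizer(f$x[rows_b, ], norm_a)
  expect_identical(xb1, xb2)
})

test_that("build_feature_matrix rejects non-standard labels", {
  rec <- dplyr::bind_rows(one_record("V1l"), one_record("artefact"))
  expect_error(build_feature_matrix(rec), "standard labels")
})

test_that("feature sets survive the text round-trip with layout sidecar", {
  f <- small_features()
  prefix <- file.path(withr::local_tempdir(), "feat")
  write_features(f, prefix)
  back <- read_features(prefix)
  expect_equal(back$x, f$x, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back$labels, f$labels)
  expect_identical(back$layout$block, f$layout$block)
  expect_identical(back$y$nerve, f$y$nerve)
})
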