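test_that("latency profiles reproduce their target moments after truncation", {
  p <- default_nerve_profiles()
  set.seed(1)
  for (key in c("R.l", "V.r")) {
    draws <- ionmqc:::draw_latency(p[[key]], 20000)
    expect_lt(abs(mean(draws) - p[[key]]$latency_mean),
              3 * p[[key]]$latency_sd / sqrt(20000) + 0.01)
    expect_lt(abs(sd(draws) - p[[key]]$latency_sd), 0.02)
    expect_gte(min(draws), p[[key]]$latency_min)
    expect_lte(max(draws), p[[key]]$latency_max)
  }
})

test_that("synth_waveform places a detectable onset at the drawn latency", {
  p <- default_nerve_profiles()$R.l
  set.seed(2)
  for (lat in c(1.5, 3.0, 8.0)) {
    w <- synth_waveform(p, lat, 1000, 2)
    det <- detect_onset_and_first_peak(w)
    expect_lt(abs(det$onset_latency - lat), 0.05)
    expect_gt(det$first_peak_latency, det$onset_latency)
    expect_lt(det$first_peak_latency, 25)
  }
})

test_that("zero-amplitude traces stay at the noise floor", {
  p <- default_nerve_profiles()$R.l
  set.seed(3)
  w <- synth_waveform(p, 3, 0, 5)
  expect_lt(max(abs(w)), 6 * 5)
  # activity decays before the end of the record for real amplitudes
  w2 <- synth_waveform(p, 3, 2000, 5)
  tail_part <- w2[801:1400]  # beyond 40 ms
  expect_lt(max(abs(tail_part)), 10 * 5)
})

test_that("detected RLN onsets stay within the clinical 1.1-10 ms band", {
  p <- default_nerve_profiles()$R.l
  set.seed(4)
  onsets <- replicate(500, {
    lat <- ionmqc:::draw_latency(p)
    detect_onset_and_first_peak(synth_waveform(p, lat, 1000, 2))$onset_latency
  })
  expect_true(all(onsets >= 1.1 & onsets <= 10))
})

test_that("flat traces yield the no-signal sentinel", {
  det <- detect_onset_and_first_peak(rep(0, 1400))
  expect_true(is.na(det$onset_latency))
  expect_true(is.na(det$first_peak_latency))
})

test_that("simulated operations follow the per-side standard sequence", {
  op <- simulate_operation(surgery_scenario("cIONM"), seed = 12)
  for (s in c("l", "r")) {
    labs <- op$label[is_standard_label(op$label) &
                       substr(op$label, 3, 3) == s]
    seq_first <- unique(substr(labs, 1, 2))
    expect_identical(seq_first, c("V1", "R1", "S1", "R2", "V2", "S2"))
    # V1 before R2 before V2 in time
    t_v1 <- min(op$stimulation_time[op$label == paste0("V1", s)])
    t_r2 <- min(op$stimulation_time[op$label == paste0("R2", s)])
    t_v2 <- min(op$stimulation_time[op$label == paste0("V2", s)])
    expect_lt(t_v1, t_r2)
    expect_lt(t_r2, t_v2)
  }
  expect_false(is.unsorted(op$stimulation_time))
})

test_that("the same seed reproduces an operation exactly", {
  sc <- surgery_scenario("cIONM")
  a <- simulate_operation(sc, seed = 55)
  b <- simulate_operation(sc, seed = 55)
  expect_identical(a, b)
  c <- simulate_operation(sc, seed = 56)
  expect_false(identical(a$stimulation_time, c$stimulation_time))
})

test_that("intermittent scenarios can store fewer than 3 signals per side", {
  sc <- surgery_scenario("iIONM", sides = "l", include_sln = FALSE,
                         signals_per_label = c(1L, 1L))
  op <- simulate_operation(sc, seed = 9)
  labelled <- op[is_standard_label(op$label), ]
  per_label <- table(labelled$label)
  expect_true(all(per_label == 1))
  expect_true(all(op$stimulating_channel[op$label == ""] %in% 1:2))
  expect_error(surgery_scenario("cIONM", sides = character()), "empty")
})

test_that("the recording channel follows the side-dependent gain", {
  op <- simulate_operation(surgery_scenario("cIONM"), seed = 21)
  lab <- op[is_standard_label(op$label), ]
  side <- substr(lab$label, 3, 3)
  # default gains: channels 1/4 serve the left side, 2/3 the right
  expect_true(all(lab$recording_channel[side == "l"] %in% c(1L, 4L)))
  expect_true(all(lab$recording_channel[side == "r"] %in% c(2L, 3L)))
})

test_that("error injection corrupts at the configured marginal rate", {
  rec <- dplyr::bind_rows(lapply(
    rep(ionm_label_vocabulary()$standard, length.out = 10000), one_record))
  rec$true_label <- rec$label
  out <- inject_label_errors(rec, error_model(rate = 0.2), seed = 8)
  frac <- mean(out$label != out$true_label)
  ci <- 2.576 * sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(frac - 0.2), ci)
  expect_identical(out$true_label, rec$true_label)
  expect_identical(out$label != out$true_label, out$label_error)
  # corrupted-to-standard labels remain inside the vocabulary
  corrupted <- out$label[out$label_error]
  std <- is_standard_label(corrupted)
  expect_true(all(corrupted[!std] %in% ionm_label_vocabulary()$annotation))
  expect_true(any(std))
})

test_that("error injection honours rate 0 and kind weights", {
  rec <- dplyr::bind_rows(lapply(rep("V1l", 200), one_record))
  rec$true_label <- rec$label
  expect_identical(inject_label_errors(rec, error_model(rate = 0)), rec)
  only_side <- inject_label_errors(
    rec, error_model(rate = 1, kind_weights = c(side = 1, nerve = 0,
                                                position = 0,
                                                annotation = 0)),
    seed = 2)
  expect_true(all(only_side$label == "V1r"))
})

test_that("corpora are deterministic and mix modalities as configured", {
  a <- simulate_corpus(10, seed = 77)
  b <- simulate_corpus(10, seed = 77)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$records$label, b$records$label)

  set.seed(1)
  big <- simulate_corpus(40, seed = 3)
  ops <- big$manifest[big$manifest$label == "<operations>", ]
  n_c <- sum(ops$n_records[ops$modality == "cIONM"])
  p_hat <- n_c / 40
  p <- 1541 / 2049
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 40))
})
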