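test_that("Welford streaming moments equal the two-pass computation", {
  # worked example: mean 5, sample sd sqrt(32/7)
  st <- welford_update(welford_init(), c(2, 4, 4, 4, 5, 5, 7, 9))
  ws <- welford_stats(st)
  expect_equal(ws$mean, 5)
  expect_equal(ws$sd, sqrt(32 / 7))
  expect_equal(ws$n, 8L)

  # single value: mean defined, sd sentinel
  one <- welford_stats(welford_update(welford_init(), 3.14))
  expect_equal(one$mean, 3.14)
  expect_true(is.na(one$sd))
  expect_true(is.na(welford_stats(welford_init())$mean))

  # random, constant and adversarially ordered streams against two-pass
  set.seed(42)
  streams <- list(
    rnorm(10000, 5, 2),
    rep(7.7, 100),
    sort(rcauchy(1000)),
    rev(sort(runif(517) * 1e6)),
    rnorm(1, 0, 1) + numeric(2) + c(0, 1e-12)
  )
  for (s in streams) {
    ws <- welford_stats(welford_update(welford_init(), s))
    expect_equal(ws$mean, mean(s), tolerance = 1e-9)
    expect_equal(ws$sd, sd(s), tolerance = 1e-9)
  }
})

test_that("MC dropout averages samples exactly and is seed-deterministic", {
  m <- tiny_trained_model()
  f <- small_features()
  x <- apply_normalizer(f$x, m$normalizer)[1:40, ]
  post <- mc_dropout_predict(m, x, n_samples = 8, seed = 5,
                             keep_samples = TRUE)
  manual <- Reduce(`+`, lapply(post$samples, `[[`, "nerve")) / 8
  expect_equal(post$mean$nerve, manual, tolerance = 1e-9)
  post2 <- mc_dropout_predict(m, x, n_samples = 8, seed = 5)
  expect_equal(post$mean, post2$mean, tolerance = 1e-12)
  post3 <- mc_dropout_predict(m, x, n_samples = 8, seed = 6)
  expect_false(isTRUE(all.equal(post$mean, post3$mean)))
  # a single sample equals the mean block
  p1 <- mc_dropout_predict(m, x, n_samples = 1, seed = 2,
                           keep_samples = TRUE)
  expect_equal(p1$mean$side, p1$samples[[1]]$side)
})

test_that("zero dropout rates make all samples identical with plain entropy", {
  f <- small_features()
  cfg <- tiny_config()
  cfg$dropout <- list(gru = 0, dense = 0, head = 0)
  plan <- tiny_plan()
  m0 <- train_model(f, plan, cfg)
  x <- apply_normalizer(f$x, m0$normalizer)[1:20, ]
  post <- mc_dropout_predict(m0, x, n_samples = 5, seed = 1,
                             keep_samples = TRUE)
  expect_equal(post$samples[[1]], post$samples[[5]], tolerance = 1e-12)
  det <- predict(m0, f)[1:20, ]
  p <- as.matrix(det[paste0("p_nerve_", c("V", "R", "S"))])
  expect_equal(
    post$raw$raw_uncertainty[post$raw$head == "nerve"],
    -rowSums(p * log(pmax(p, 1e-12))),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  # a model config stripped of dropout is refused
  m_bad <- m0
  m_bad$config$dropout <- NULL
  expect_error(mc_dropout_predict(m_bad, x), "dropout")
})

test_that("the uniform head has entropy ln 3", {
  p <- matrix(1 / 3, 1, 3)
  expect_equal(-sum(p * log(p)), log(3), tolerance = 1e-12)
  # and the posterior reports it for a uniform mean distribution
  u <- -rowSums(p * log(pmax(p, 1e-12)))
  expect_equal(u, log(3))
})

test_that("calibration cells carry Welford moments of the subset uncertainties", {
  m <- tiny_trained_model()
  f <- small_features()
  plan <- tiny_plan()
  calib <- fit_calibration(m, f, rows = plan$train, subset_size = 60,
                           n_samples = 5, seed = 2)
  expect_equal(nrow(calib), 7)   # 3 + 2 + 2 head/class cells
  expect_equal(sum(calib$n), 60 * 3)
  expect_true(all(calib$sigma[calib$fitted] > 0))
  expect_true(all(calib$n[calib$fitted] >= 2))
  # unfitted cells are flagged, never silently used
  expect_true(all(calib$fitted | calib$n < 2 | calib$degenerate |
                    is.na(calib$sigma) | calib$sigma == 0))
  expect_error(
    fit_calibration(m, f, rows = plan$train,
                    subset_size = length(plan$train) + 1),
    "subset_size")
})

test_that("calibrate maps mu to 0.5, mu+1.96 sigma to 0.975, monotonically", {
  calib <- structure(
    tibble::tibble(head = "nerve", class = "V", n = 100L, mu = 0.4,
                   sigma = 0.1, fitted = TRUE, degenerate = FALSE),
    class = c("ionm_calibration", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(calibrate_uncertainty(0.4, "nerve", "V", calib), 0.5)
  expect_equal(calibrate_uncertainty(0.4 + 1.96 * 0.1, "nerve", "V", calib),
               0.975, tolerance = 1e-3)
  expect_equal(calibrate_uncertainty(-1e6, "nerve", "V", calib), 0)
  expect_equal(calibrate_uncertainty(1e6, "nerve", "V", calib), 1)
  grid <- calibrate_uncertainty(seq(0, 1, 0.01), rep("nerve", 101),
                                rep("V", 101), calib)
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= 0 & grid <= 1))
  # unfitted cell: NA sentinel with warning
  calib$fitted <- FALSE
  expect_warning(out <- calibrate_uncertainty(0.4, "nerve", "V", calib),
                 "manual review")
  expect_true(is.na(out))
})

test_that("calibrated subset uncertainties are near-uniform under the Gaussian model", {
  m <- tiny_trained_model()
  f <- small_features()
  plan <- tiny_plan()
  calib <- fit_calibration(m, f, rows = plan$train,
                           subset_size = min(200, length(plan$train)),
                           n_samples = 8, seed = 3)
  x <- apply_normalizer(f$x, m$normalizer)[plan$train, ]
  post <- mc_dropout_predict(m, x, n_samples = 8, seed = 4)
  cal <- calibrate_posterior(post, calib)
  vals <- cal$calibrated[cal$head == "nerve" & !is.na(cal$calibrated)]
  ks <- suppressWarnings(stats::ks.test(vals, "punif"))
  expect_lt(unname(ks$statistic), 0.35)
})

test_that("review flags respect the threshold limits", {
  cal <- tibble::tibble(
    row = rep(1:3, each = 3),
    head = rep(c("nerve", "side", "position"), 3),
    calibrated = c(0.1, 0.2, 0.3, 0.99, 0.1, 0.1, NA, 0.5, 0.5)
  )
  all_off <- flag_for_review(cal, 1.0)
  expect_identical(all_off$review_flag, c(FALSE, FALSE, TRUE))  # NA flagged
  all_on <- flag_for_review(dplyr::filter(cal, !is.na(.data$calibrated)), 0)
  expect_true(all(all_on$review_flag))
  mid <- flag_for_review(cal, 0.9)
  expect_identical(mid$review_flag, c(FALSE, TRUE, TRUE))
  expect_error(flag_for_review(cal, 1.5), "threshold")
})

test_that("calibration tables survive the JSON round-trip", {
  m <- tiny_trained_model()
  f <- small_features()
  plan <- tiny_plan()
  calib <- fit_calibration(m, f, rows = plan$train, subset_size = 40,
                           n_samples = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  save_calibration(calib, path)
  back <- load_calibration(path)
  expect_equal(back$mu, calib$mu, tolerance = 1e-12)
  expect_equal(attr(back, "subset_size"), 40L)
  expect_equal(tidy(back), tidy(calib), tolerance = 1e-12)
})
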