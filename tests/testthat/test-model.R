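test_that("split sizes follow the ceiling/round conventions, checked by brute force", {
  for (n in c(10, 11, 37, 100, 333, 1000)) {
    plan <- make_split(n, seed = 3)
    expect_equal(length(plan$train), ceiling(0.7 * n))
    expect_equal(length(plan$test), n - ceiling(0.7 * n))
    expect_equal(length(plan$validation), round(0.2 * ceiling(0.7 * n)))
    expect_length(intersect(plan$train, plan$test), 0)
    expect_setequal(c(plan$train, plan$test), seq_len(n))
    expect_true(all(plan$validation %in% plan$train))
  }
  # the published data accounting: 16305 -> 11414 / 4891 with 2283 validation
  plan <- make_split(16305, seed = 1)
  expect_equal(length(plan$train), 11414)
  expect_equal(length(plan$test), 4891)
  expect_equal(length(plan$validation), 2283)

  expect_identical(make_split(500, seed = 8), make_split(500, seed = 8))
  expect_error(make_split(5), "at least 10")
})

test_that("analytic gradients match central finite differences across all layers", {
  cfg <- model_config(gru_units = c(3L, 2L), conv_filters = c(3L, 2L),
                      kernel_sizes = c(3L, 3L), dense_units = 4L,
                      dropout = list(gru = 0, dense = 0, head = 0),
                      l1 = 1e-3, l2 = 1e-3, seed = 42)
  set.seed(42)
  b <- 5L; tl <- 12L; cx <- 4L
  params <- ionmqc:::init_params(cfg, 1L, tl, cx)
  state <- ionmqc:::init_bn_state(cfg)
  xs <- matrix(rnorm(b * tl), b, tl)
  xc <- matrix(rnorm(b * cx), b, cx)
  y <- list(
    nerve = ionmqc:::onehot(sample(c("V", "R", "S"), b, TRUE),
                            c("V", "R", "S")),
    side = ionmqc:::onehot(sample(c("l", "r"), b, TRUE), c("l", "r")),
    position = ionmqc:::onehot(sample(c("1", "2"), b, TRUE), c("1", "2"))
  )
  lossfn <- function(p) {
    fw <- ionmqc:::nn_forward(p, state, xs, xc, cfg, mode = "train")
    ionmqc:::nn_loss(fw$probs, y, p, cfg)
  }
  fw <- ionmqc:::nn_forward(params, state, xs, xc, cfg, mode = "train")
  gr <- ionmqc:::nn_backward(fw$probs, y, fw$cache, params, cfg)
  eps <- 1e-6
  for (nm in names(params)) {
    p <- params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      pp <- params; pp[[nm]][i] <- p[i] + eps
      pm <- params; pm[[nm]][i] <- p[i] - eps
      num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) / max(abs(num) + abs(gr[[nm]][i]), 1e-8),
                1e-4)
    }
  }
})

test_that("untrained models emit normalized probability heads of sizes 3/2/2", {
  f <- small_features()
  model <- build_model(tiny_config(), f$layout)
  norm <- fit_normalizer(f$x, f$layout$feature)
  x <- apply_normalizer(f$x, norm)
  xin <- ionmqc:::model_inputs(model, x)
  fw <- ionmqc:::nn_forward(model$params, model$state, xin$seq, xin$ctx,
                            model$config, mode = "infer")
  expect_equal(ncol(fw$probs$nerve), 3)
  expect_equal(ncol(fw$probs$side), 2)
  expect_equal(ncol(fw$probs$position), 2)
  for (h in names(fw$probs)) {
    expect_equal(rowSums(fw$probs[[h]]), rep(1, nrow(x)), tolerance = 1e-6)
  }
  expect_error(model_config(conv_filters = c(0L, 4L)), "positive")
})

test_that("training learns the synthetic task and records its history", {
  m <- tiny_trained_model()
  expect_true(m$trained)
  expect_lte(nrow(m$history), m$config$epochs)
  expect_lte(m$best_epoch, nrow(m$history))
  # loss went down from the first epoch
  expect_lt(min(m$history$val_loss), m$history$val_loss[1])
  # the normalizer was fitted on training rows only
  f <- small_features()
  plan <- tiny_plan()
  expected <- fit_normalizer(
    f$x[plan$train, ],
    f$layout$feature[!f$layout$block %in% c("channel_onehot",
                                            "modality_onehot")])
  expect_equal(m$normalizer, expected)
})

test_that("prediction is deterministic and decodes into the vocabulary", {
  m <- tiny_trained_model()
  f <- small_features()
  p1 <- predict(m, f)
  p2 <- predict(m, f)
  expect_identical(p1, p2)
  expect_true(all(is_standard_label(p1$pred_label)))
  expect_equal(p1$p_nerve_V + p1$p_nerve_R + p1$p_nerve_S,
               rep(1, nrow(p1)), tolerance = 1e-6)
  # layout mismatch is refused
  bad <- f$x[, c(2:216, 1)]
  expect_error(predict(m, bad), "layout")
})

test_that("permuted labels drive validation accuracy to the majority rate", {
  f <- small_features()
  set.seed(31)
  fp <- f
  perm <- sample(nrow(f$x))
  fp$y <- lapply(f$y, function(m) m[perm, , drop = FALSE])
  fp$labels <- f$labels[perm]
  plan <- make_split(nrow(f$x), seed = 4)
  m <- train_model(fp, plan, tiny_config(epochs = 3L))
  hb <- m$history[m$best_epoch, ]
  base_side <- max(mean(split_label(fp$labels)$side[plan$validation] == "l"),
                   mean(split_label(fp$labels)$side[plan$validation] == "r"))
  expect_lt(hb$val_acc_side, base_side + 0.12)
})

test_that("repeated runs produce the 3-output x 2-phase mean(sd) table", {
  f <- small_features()
  runs <- repeated_runs(f, k = 2L, base_seed = 21,
                        config = tiny_config(epochs = 2L))
  expect_equal(nrow(runs$table), 6)
  expect_setequal(runs$table$output, c("nerve", "side", "position"))
  expect_setequal(runs$table$phase, c("training", "validation"))
  expect_true(all(runs$table$mean >= 0 & runs$table$mean <= 100))
  expect_true(all(grepl("^\\d+\\.\\d{2}\\(", runs$table$formatted)))
  # k = 1 renders the sd column as not applicable
  one <- repeated_runs(f, k = 1L, base_seed = 5,
                       config = tiny_config(epochs = 2L))
  expect_true(all(is.na(one$table$sd)))
  expect_true(all(grepl("n/a", one$table$formatted)))
})

test_that("a checkpoint round-trips through JSON with identical predictions", {
  m <- tiny_trained_model()
  f <- small_features()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(predict(back, f), predict(m, f), tolerance = 1e-9)
  expect_equal(back$best_epoch, m$best_epoch)
})

test_that("tidy and glance summarize a fitted model", {
  m <- tiny_trained_model()
  td <- tidy(m)
  expect_true(all(c("epoch", "metric", "value") %in% names(td)))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_true(gl$trained)
  expect_equal(gl$n_features, 216)
})
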