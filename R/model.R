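#' Configure the multitask classifier
#'
#' Architecture and training hyperparameters of the multitask 1-D
#' convolutional-recurrent network: the downsampled EMG segment is fed as an
#' ordered sequence through two gated recurrent unit layers and two
#' convolution + batch-normalization + max-pooling blocks; the flattened
#' trunk output is joined with the context and categorical features and
#' split into three softmax branches (nerve 3 classes, side 2, position 2).
#' Per-head cross-entropy losses are summed with equal weights and minimized
#' with Adam; the learning rate halves on a validation-loss plateau and the
#' parameters of the best validation epoch are kept.
#'
#' @param gru_units Sizes of the two recurrent layers.
#' @param conv_filters,kernel_sizes Filters and kernel widths of the two
#'   convolution blocks.
#' @param pool_size Max-pooling width.
#' @param dense_units Hidden units of each branch head.
#' @param dropout Named list of dropout rates (`gru`, `dense`, `head`), each
#'   in `[0, 1)`.
#' @param l1,l2 Regularization coefficients on weight matrices.
#' @param epochs Training epochs (default 80).
#' @param batch_size Minibatch size.
#' @param lr Initial Adam learning rate.
#' @param lr_reduction List with `factor`, `patience`, `min_lr` for the
#'   reduce-on-plateau schedule.
#' @param feed_mode `"split"` feeds the EMG segment to the trunk and joins
#'   the remaining features before the heads; `"sequence_all"` feeds the
#'   whole feature row as one sequence.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return An object of class `ionm_model_config`.
#' @export
model_config <- function(gru_units = c(24L, 16L),
                         conv_filters = c(16L, 16L),
                         kernel_sizes = c(5L, 5L),
                         pool_size = 2L,
                         dense_units = 32L,
                         dropout = list(gru = 0.15, dense = 0.3, head = 0.2),
                         l1 = 1e-6, l2 = 1e-5,
                         epochs = 80L, batch_size = 256L, lr = 3e-3,
                         lr_reduction = list(factor = 0.5, patience = 5L,
                                             min_lr = 1e-5),
                         feed_mode = c("split", "sequence_all"),
                         seed = 1L) {
  if (any(conv_filters <= 0)) abort("conv_filters must be positive")
  if (any(gru_units <= 0)) abort("gru_units must be positive")
  if (epochs < 1) abort("epochs must be >= 1")
  rates <- unlist(dropout)
  if (is.null(dropout) || any(rates < 0) || any(rates >= 1)) {
    abort("dropout rates must lie in [0, 1)")
  }
  structure(
    list(gru_units = as.integer(gru_units),
         conv_filters = as.integer(conv_filters),
         kernel_sizes = as.integer(kernel_sizes),
         pool_size = as.integer(pool_size),
         dense_units = as.integer(dense_units),
         dropout = dropout, l1 = l1, l2 = l2,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, lr_reduction = lr_reduction,
         feed_mode = match.arg(feed_mode), seed = as.integer(seed)),
    class = "ionm_model_config"
  )
}

#' Random train/test split with internal validation subset
#'
#' Indices are permuted uniformly at random under the seed. The training set
#' holds `ceiling(0.7 n)` rows, the test set the remainder, and
#' `round(0.2 |train|)` training rows form the internal validation subset
#' (e.g. 16 305 rows give 11 414 train / 4 891 test / 2 283 validation).
#'
#' @param n Number of rows (at least 10).
#' @param seed Integer seed.
#' @param train_fraction,validation_fraction Split fractions.
#' @return An object of class `split_plan` with `train`, `test`,
#'   `validation` (a subset of `train`) index vectors.
#' @export
make_split <- function(n, seed = 1L, train_fraction = 0.7,
                       validation_fraction = 0.2) {
  if (n < 10) abort("need at least 10 records to split")
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- ceiling(train_fraction * n)
  train <- perm[seq_len(n_train)]
  test <- perm[(n_train + 1):n]
  n_val <- round(validation_fraction * n_train)
  structure(
    list(train = train, test = test, validation = train[seq_len(n_val)],
         seed = as.integer(seed), n = as.integer(n)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> n=%d: train %d (validation %d) / test %d\n",
              x$n, length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

split_feature_columns <- function(layout, feed_mode) {
  if (feed_mode == "sequence_all") {
    return(list(seq = seq_len(nrow(layout)), ctx = integer(0)))
  }
  seq_cols <- which(layout$block == "emg_segment")
  if (length(seq_cols) == 0) {
    abort("feed_mode 'split' needs an emg_segment block; use 'sequence_all'")
  }
  list(seq = seq_cols, ctx = setdiff(seq_len(nrow(layout)), seq_cols))
}

#' Build an untrained multitask network
#'
#' Initializes all parameters for the given feature layout. The untrained
#' model already produces valid probability heads (each row sums to 1).
#'
#' @param config A [model_config()].
#' @param layout Feature layout tibble from an `ionm_features` object.
#' @return An object of class `ionm_model` with `trained = FALSE`.
#' @export
build_model <- function(config = model_config(), layout) {
  cols <- split_feature_columns(layout, config$feed_mode)
  set.seed(config$seed)
  params <- init_params(config, n_seq_channels = 1L,
                        t_len = length(cols$seq), n_ctx = length(cols$ctx))
  structure(
    list(params = params, state = init_bn_state(config), config = config,
         layout = layout, columns = cols, normalizer = NULL,
         trained = FALSE, history = NULL, best_epoch = NA_integer_),
    class = "ionm_model"
  )
}

model_inputs <- function(model, x) {
  if (ncol(x) != nrow(model$layout)) {
    abort(sprintf("feature width %d does not match the model's layout (%d)",
                  ncol(x), nrow(model$layout)))
  }
  if (!identical(colnames(x), model$layout$feature)) {
    abort("feature names do not match the model's layout sidecar")
  }
  list(seq = x[, model$columns$seq, drop = FALSE],
       ctx = x[, model$columns$ctx, drop = FALSE])
}

feature_matrix_for <- function(model, features) {
  if (is.null(features$normalizer)) {
    if (is.null(model$normalizer)) {
      abort("features are raw and the model carries no normalizer")
    }
    return(apply_normalizer(features$x, model$normalizer))
  }
  if (!is.null(model$normalizer) &&
      !isTRUE(all.equal(features$normalizer$min, model$normalizer$min,
                        tolerance = 1e-12))) {
    abort("features were normalized with parameters different from the model's")
  }
  features$x
}

head_accuracy <- function(probs, y) {
  vapply(names(probs), function(h) {
    mean(max.col(probs[[h]]) == max.col(y[[h]]))
  }, numeric(1))
}

subset_y <- function(y, rows) lapply(y, function(m) m[rows, , drop = FALSE])

#' Train the multitask classifier
#'
#' Fits the network on the training rows of the split (minus the internal
#' validation subset, which monitors the loss), with min-max normalization
#' fitted on the training rows only. The learning rate is halved when the
#' validation loss plateaus, and the parameters of the epoch with the best
#' validation loss are restored at the end. Aborts with a diagnostic if the
#' loss turns non-finite.
#'
#' @param features An `ionm_features` object, raw (preferred; the normalizer
#'   is then fitted here on training rows only) or pre-normalized.
#' @param plan A [make_split()] plan for `nrow(features$x)`.
#' @param config A [model_config()].
#' @param quiet Suppress per-epoch progress.
#' @return A trained `ionm_model` carrying parameters, batch-norm state,
#'   normalizer, per-epoch `history` and `best_epoch`.
#' @export
train_model <- function(features, plan, config = model_config(),
                        quiet = TRUE) {
  stopifnot(inherits(features, "ionm_features"), inherits(plan, "split_plan"))
  if (plan$n != nrow(features$x)) abort("split plan size mismatch")
  model <- build_model(config, features$layout)
  if (is.null(features$normalizer)) {
    onehot_blocks <- c("channel_onehot", "modality_onehot")
    numeric_features <-
      features$layout$feature[!features$layout$block %in% onehot_blocks]
    model$normalizer <- fit_normalizer(
      features$x[plan$train, , drop = FALSE], numeric_features)
    x <- apply_normalizer(features$x, model$normalizer)
  } else {
    model$normalizer <- features$normalizer
    x <- features$x
  }
  xin <- model_inputs(model, x)
  fit_rows <- setdiff(plan$train, plan$validation)
  val_rows <- plan$validation
  y <- features$y

  set.seed(config$seed)
  params <- model$params
  state <- model$state
  opt <- adam_init(params)
  lr <- config$lr
  best <- list(loss = Inf, params = params, state = state, epoch = 0L)
  wait <- 0L
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(fit_rows)
    nb <- ceiling(length(ord) / config$batch_size)
    ep_loss <- 0
    ep_acc <- c(nerve = 0, side = 0, position = 0)
    for (b in seq_len(nb)) {
      rows <- ord[((b - 1) * config$batch_size + 1):
                    min(b * config$batch_size, length(ord))]
      fw <- nn_forward(params, state,
                       xin$seq[rows, , drop = FALSE],
                       xin$ctx[rows, , drop = FALSE],
                       config, mode = "train")
      state <- fw$state
      yb <- subset_y(y, rows)
      loss <- nn_loss(fw$probs, yb, params, config)
      if (!is.finite(loss)) {
        abort(sprintf("non-finite loss at epoch %d batch %d (lr=%g)",
                      epoch, b, lr))
      }
      grads <- nn_backward(fw$probs, yb, fw$cache, params, config)
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params
      opt <- upd$opt
      w <- length(rows) / length(ord)
      ep_loss <- ep_loss + loss * w
      ep_acc <- ep_acc + head_accuracy(fw$probs, yb) * w
    }
    vp <- nn_forward_chunked(params, state, xin$seq[val_rows, , drop = FALSE],
                             xin$ctx[val_rows, , drop = FALSE], config,
                             mode = "infer")
    yv <- subset_y(y, val_rows)
    val_loss <- nn_loss(vp, yv, params, config)
    val_acc <- head_accuracy(vp, yv)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = ep_loss, val_loss = val_loss,
      train_acc_nerve = ep_acc[["nerve"]], train_acc_side = ep_acc[["side"]],
      train_acc_position = ep_acc[["position"]],
      val_acc_nerve = val_acc[["nerve"]], val_acc_side = val_acc[["side"]],
      val_acc_position = val_acc[["position"]]
    )
    if (!quiet) {
      inform(sprintf(
        "epoch %02d lr=%.2g loss=%.4f val_loss=%.4f val_acc=%.3f/%.3f/%.3f",
        epoch, lr, ep_loss, val_loss, val_acc[1], val_acc[2], val_acc[3]))
    }
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = params, state = state,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$lr_reduction$patience) {
        lr <- max(lr * config$lr_reduction$factor,
                  config$lr_reduction$min_lr)
        wait <- 0L
      }
    }
  }
  model$params <- best$params
  model$state <- best$state
  model$best_epoch <- best$epoch
  model$history <- dplyr::bind_rows(hist)
  model$trained <- TRUE
  model$plan <- plan
  model
}

#' @export
print.ionm_model <- function(x, ...) {
  cat(sprintf(
    "<ionm_model> %s multitask GRU(%s)+conv(%s) network, %d features\n",
    if (x$trained) "trained" else "untrained",
    paste(x$config$gru_units, collapse = "/"),
    paste(x$config$conv_filters, collapse = "/"),
    nrow(x$layout)
  ))
  if (x$trained) {
    cat(sprintf("  best epoch %d of %d; validation accuracy %.3f/%.3f/%.3f (nerve/side/position)\n",
                x$best_epoch, nrow(x$history),
                x$history$val_acc_nerve[x$best_epoch],
                x$history$val_acc_side[x$best_epoch],
                x$history$val_acc_position[x$best_epoch]))
  }
  invisible(x)
}

#' Predict labels for feature rows
#'
#' Plain deterministic inference (no dropout): per-head class probabilities,
#' per-head argmax classes, and the decoded three-character label.
#'
#' @param object A trained `ionm_model`.
#' @param features An `ionm_features` object (raw features are normalized
#'   with the model's stored parameters) or a pre-normalized matrix matching
#'   the layout.
#' @param ... Unused.
#' @return A tibble with one row per record: `p_nerve_V/R/S`, `p_side_l/r`,
#'   `p_position_1/2`, `pred_nerve`, `pred_side`, `pred_position`,
#'   `pred_label`.
#' @export
predict.ionm_model <- function(object, features, ...) {
  x <- if (inherits(features, "ionm_features")) {
    feature_matrix_for(object, features)
  } else {
    features
  }
  xin <- model_inputs(object, x)
  probs <- nn_forward_chunked(object$params, object$state, xin$seq, xin$ctx,
                              object$config, mode = "infer")
  probs_to_predictions(probs)
}

probs_to_predictions <- function(probs) {
  cls <- list(nerve = c("V", "R", "S"), side = c("l", "r"),
              position = c("1", "2"))
  out <- tibble::tibble(.rows = nrow(probs$nerve))
  for (h in names(cls)) {
    p <- probs[[h]]
    colnames(p) <- paste0("p_", h, "_", cls[[h]])
    out <- dplyr::bind_cols(out, tibble::as_tibble(p))
    out[[paste0("pred_", h)]] <- cls[[h]][max.col(p)]
  }
  out$pred_label <- join_label(out$pred_nerve, out$pred_side,
                               out$pred_position)
  out
}

#' Repeat the train/evaluate cycle over independent splits
#'
#' Re-splits, re-initializes and re-trains `k` times (default 15) and
#' reports the mean and standard deviation of the per-head accuracy for the
#' training and validation phases, in the shape of the published run table.
#'
#' @param features An `ionm_features` object (raw).
#' @param k Number of runs (>= 2 for a standard deviation).
#' @param base_seed Seed; run `i` uses `base_seed + i` for its split and
#'   initialization.
#' @param config A [model_config()].
#' @return A list of class `ionm_runs`: `table` (output x phase with
#'   mean/sd and a `mean(sd)` string) and `runs` (per-run accuracies).
#' @export
repeated_runs <- function(features, k = 15L, base_seed = 1L,
                          config = model_config()) {
  if (k < 1) abort("k must be >= 1")
  n <- nrow(features$x)
  runs <- vector("list", k)
  for (i in seq_len(k)) {
    cfg <- config
    cfg$seed <- config$seed + i
    plan <- make_split(n, seed = base_seed + i)
    fit <- train_model(features, plan, cfg)
    hb <- fit$history[fit$best_epoch, ]
    runs[[i]] <- tibble::tibble(
      run = i,
      output = rep(c("nerve", "side", "position"), 2),
      phase = rep(c("training", "validation"), each = 3),
      accuracy = 100 * c(hb$train_acc_nerve, hb$train_acc_side,
                         hb$train_acc_position, hb$val_acc_nerve,
                         hb$val_acc_side, hb$val_acc_position)
    )
  }
  runs <- dplyr::bind_rows(runs)
  table <- runs |>
    dplyr::group_by(.data$output, .data$phase) |>
    dplyr::summarise(
      mean = mean(.data$accuracy),
      sd = if (dplyr::n() > 1) sd(.data$accuracy) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(formatted = ifelse(
      is.na(.data$sd), sprintf("%.2f(n/a)", .data$mean),
      sprintf("%.2f(%.2f)", .data$mean, .data$sd)
    ))
  structure(list(table = table, runs = runs, k = k), class = "ionm_runs")
}

#' @export
print.ionm_runs <- function(x, ...) {
  cat(sprintf("<ionm_runs> accuracy over %d runs, %% mean(sd)\n", x$k))
  print(as.data.frame(x$table))
  invisible(x)
}

# Checkpoint persistence ----------------------------------------------------

#' Save / load a trained model as JSON
#'
#' The checkpoint stores parameters (17 significant digits), batch-norm
#' state, configuration, feature layout and normalizer, so a reloaded model
#' reproduces predictions to numerical round-off.
#'
#' @param model A trained `ionm_model`.
#' @param path Checkpoint path (JSON).
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  ser <- list(
    params = lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.numeric(p))
    }),
    state = model$state,
    config = unclass(model$config),
    layout = model$layout,
    columns = model$columns,
    normalizer = model$normalizer,
    trained = model$trained,
    best_epoch = model$best_epoch,
    history = model$history
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(ser$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  cfg <- ser$config
  config <- model_config(
    gru_units = cfg$gru_units, conv_filters = cfg$conv_filters,
    kernel_sizes = cfg$kernel_sizes, pool_size = cfg$pool_size,
    dense_units = cfg$dense_units, dropout = as.list(cfg$dropout),
    l1 = cfg$l1, l2 = cfg$l2, epochs = cfg$epochs,
    batch_size = cfg$batch_size, lr = cfg$lr,
    lr_reduction = as.list(cfg$lr_reduction), feed_mode = cfg$feed_mode,
    seed = cfg$seed
  )
  structure(
    list(
      params = params,
      state = lapply(ser$state, function(s) lapply(s, as.numeric)),
      config = config,
      layout = tibble::as_tibble(ser$layout),
      columns = lapply(ser$columns, as.integer),
      normalizer = if (is.null(ser$normalizer)) NULL else
        tibble::as_tibble(ser$normalizer),
      trained = isTRUE(ser$trained),
      history = if (is.null(ser$history)) NULL else
        tibble::as_tibble(ser$history),
      best_epoch = ser$best_epoch
    ),
    class = "ionm_model"
  )
}
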