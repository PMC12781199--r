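# Waveform-level operators ------------------------------------------------

#' Truncate a waveform to 25 ms and keep one sample in four
#'
#' The evoked peaks lie inside the first 25 ms of the 70 ms record; the
#' remaining time carries no relevant activity. The first 500 samples are
#' kept and thinned to every 4th value (the first of each group of four),
#' giving 125 values per signal.
#'
#' @param waveform Numeric vector of 1400 samples, or a list of them.
#' @return Numeric vector of 125 values (or a 125-column matrix for a list).
#' @export
truncate_downsample <- function(waveform) {
  idx <- seq(1L, 500L, by = 4L)
  if (is.list(waveform)) {
    len <- lengths(waveform)
    if (any(len != WAVEFORM_N)) abort("waveform length must be 1400")
    return(t(vapply(waveform, function(w) w[idx], numeric(125L))))
  }
  if (length(waveform) != WAVEFORM_N) abort("waveform length must be 1400")
  waveform[idx]
}

#' Detect onset and first-peak latency from a waveform
#'
#' The onset is the first time the rectified signal exceeds `k` times the
#' noise standard deviation estimated over the pre-response window, with
#' `min_run` consecutive supra-threshold samples required (rejecting isolated
#' noise excursions) and the crossing refined by linear interpolation between
#' the bracketing samples (sub-sample resolution). The first peak is the
#' first supra-threshold local extremum of the rectified signal at or after
#' the onset. Device-reported latencies can be incorrect, so downstream
#' feature extraction uses these recomputed values.
#'
#' @param waveform Numeric vector of 1400 samples, or a list of them.
#' @param noise_window Pre-response window used to estimate noise, in ms.
#' @param k Threshold multiplier on the noise standard deviation.
#' @param min_run Consecutive supra-threshold samples required.
#' @return A tibble with columns `onset_latency` and `first_peak_latency`
#'   (ms; `NA` sentinel when no threshold crossing exists).
#' @export
detect_onset_and_first_peak <- function(waveform, noise_window = 1, k = 5,
                                        min_run = 3L) {
  if (is.list(waveform)) {
    out <- vapply(waveform, detect_onset_one, numeric(2),
                  noise_window = noise_window, k = k, min_run = min_run)
    return(tibble::tibble(onset_latency = out[1, ],
                          first_peak_latency = out[2, ]))
  }
  out <- detect_onset_one(waveform, noise_window, k, min_run)
  tibble::tibble(onset_latency = out[1], first_peak_latency = out[2])
}

detect_onset_one <- function(w, noise_window, k, min_run) {
  if (length(w) != WAVEFORM_N) abort("waveform length must be 1400")
  nw <- max(2L, round(noise_window / WAVEFORM_DT))
  thr <- k * sd(w[seq_len(nw)])
  a <- abs(w)
  above <- a > thr
  ok <- above
  if (min_run > 1) {
    for (j in seq_len(min_run - 1)) {
      ok <- ok & c(above[-seq_len(j)], rep(FALSE, j))
    }
  }
  i <- which(ok)[1]
  if (is.na(i)) return(c(NA_real_, NA_real_))
  onset <- if (i == 1L) {
    0
  } else {
    frac <- (thr - a[i - 1]) / (a[i] - a[i - 1])
    (i - 2 + frac) * WAVEFORM_DT
  }
  n <- length(a)
  jseq <- seq(max(i, 2L), n - 1L)
  peak <- jseq[a[jseq] >= a[jseq - 1] & a[jseq] >= a[jseq + 1] &
                 above[jseq]][1]
  fp <- if (is.na(peak)) NA_real_ else (peak - 1) * WAVEFORM_DT
  c(onset, fp)
}

# Operation-level context --------------------------------------------------

#' Summarize the temporospatial context of each operation
#'
#' For every operation this computes the per-channel summary amplitude over
#' all stored records (channels never used get 0), the operation duration,
#' and for each of the 12 standard labels up to `time_points_per_label`
#' normalized occurrence times (occurrence time divided by duration, in
#' `[0, 1]`; absent slots carry the padding `sentinel`), plus capped
#' occurrence counts and simple whole-operation summaries.
#'
#' @param records A records tibble covering the full operation(s), labelled
#'   and unlabelled records alike.
#' @param stat `"mean"` (default) or `"median"` per-channel amplitude.
#' @param time_points_per_label Slots per standard label (default 4).
#' @param sentinel Padding value for absent time points (outside `[0, 1]`).
#' @return A tibble with one row per `operation_id`.
#' @export
compute_operation_context <- function(records, stat = c("mean", "median"),
                                      time_points_per_label = 4L,
                                      sentinel = -1) {
  stat <- match.arg(stat)
  fun <- if (stat == "mean") mean else median
  vocab <- ionm_label_vocabulary()$standard
  k <- time_points_per_label
  dur <- operation_duration(records)
  if (any(dur$duration <= 0)) abort("operation with zero duration")
  ops <- split(records, records$operation_id)
  rows <- lapply(names(ops), function(id) {
    op <- ops[[id]]
    d <- max(op$stimulation_time)
    ch <- vapply(1:4, function(c) {
      v <- op$amplitude[op$recording_channel == c]
      if (length(v) == 0) 0 else fun(v)
    }, numeric(1))
    lt <- numeric(0)
    lc <- numeric(0)
    for (lab in vocab) {
      tt <- sort(op$stimulation_time[op$label == lab])
      pts <- rep(sentinel, k)
      kk <- min(length(tt), k)
      if (kk > 0) pts[seq_len(kk)] <- tt[seq_len(kk)] / d
      lt <- c(lt, pts)
      lc <- c(lc, min(length(tt), 4) / 4)
    }
    row <- c(ch, d, lt, lc,
             max(op$amplitude), nrow(op),
             mean(is_standard_label(op$label)))
    names(row) <- c(
      paste0("ctx_ch_mean_", 1:4), "ctx_duration",
      paste0("ctx_tp_", rep(vocab, each = k), "_", rep(seq_len(k), 12)),
      paste0("ctx_count_", vocab),
      "ctx_max_amplitude", "ctx_n_records", "ctx_labelled_fraction"
    )
    dplyr::bind_cols(tibble::tibble(operation_id = id),
                     tibble::as_tibble_row(as.list(row)))
  })
  dplyr::bind_rows(rows)
}

# Feature configuration ----------------------------------------------------

#' Configure the feature layout
#'
#' The default layout totals 216 features: 125 downsampled waveform values,
#' 4 channel summary amplitudes, 1 recomputed first-peak latency, 48 label
#' time points (12 labels x 4 slots), normalized stimulation time,
#' stimulation current, amplitude (3), one-hot recording channel (4),
#' stimulating channel (2) and modality (2), plus 27 engineered context
#' features (per-label capped counts, device latencies, recomputed onset,
#' segment shape summaries, neighbour timing, amplitude ratios, operation
#' duration and the record's relative time inside each side's labelled
#' block). Blocks can be switched off and the number of
#' time-point slots changed, reaching widths across roughly 150-280; widths
#' outside that range trigger a warning.
#'
#' @param emg_segment,channel_means,first_peak,label_time_points,
#'   stimulus_fields,channel_onehot,modality_onehot,extra_context Logical
#'   switches for the feature blocks.
#' @param time_points_per_label Slots per label in the time-point block.
#' @param context_stat `"mean"` or `"median"` channel amplitude summary.
#' @param sentinel Padding value for absent time points.
#' @return An object of class `ionm_feature_config`.
#' @export
feature_config <- function(emg_segment = TRUE, channel_means = TRUE,
                           first_peak = TRUE, label_time_points = TRUE,
                           stimulus_fields = TRUE, channel_onehot = TRUE,
                           modality_onehot = TRUE, extra_context = TRUE,
                           time_points_per_label = 4L,
                           context_stat = c("mean", "median"),
                           sentinel = -1) {
  structure(
    list(
      emg_segment = emg_segment, channel_means = channel_means,
      first_peak = first_peak, label_time_points = label_time_points,
      stimulus_fields = stimulus_fields, channel_onehot = channel_onehot,
      modality_onehot = modality_onehot, extra_context = extra_context,
      time_points_per_label = as.integer(time_points_per_label),
      context_stat = match.arg(context_stat), sentinel = sentinel
    ),
    class = "ionm_feature_config"
  )
}

onehot <- function(x, levels) {
  m <- matrix(0, length(x), length(levels))
  hit <- match(x, levels)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  colnames(m) <- levels
  m
}

# Feature matrix -----------------------------------------------------------

#' Build the model's feature matrix and one-hot target blocks
#'
#' Converts standard-labelled records into a fixed-width numeric matrix (one
#' row per record) and the three one-hot target blocks (nerve over V/R/S,
#' side over l/r, position over 1/2). Numeric features are min-max scaled to
#' `[0, 1]` with parameters fitted on the provided rows, or with a previously
#' fitted `normalizer` for held-out data (never refit silently). One-hot
#' indicator columns are left untouched.
#'
#' @param records Standard-labelled records (see [filter_standard_labels()]).
#' @param context Per-operation context tibble from
#'   [compute_operation_context()] on the *full* operations. When `NULL` it
#'   is computed from `records` alone (labelled records only).
#' @param config An [feature_config()].
#' @param normalizer A previously fitted normalizer, or `NULL` to fit here.
#' @param normalize Set `FALSE` to return raw features (the training stage
#'   then fits the normalizer on the training rows only).
#' @return An object of class `ionm_features`: a list with the feature
#'   matrix `x`, target blocks `y` (`$nerve`, `$side`, `$position`), the
#'   stored `labels`, a `layout` tibble (feature name and block), the fitted
#'   `normalizer` (or `NULL`), per-row `meta`, and the `config`.
#' @export
build_feature_matrix <- function(records, context = NULL,
                                 config = feature_config(),
                                 normalizer = NULL, normalize = TRUE) {
  if (nrow(records) == 0) abort("no records to featurize")
  if (!all(is_standard_label(records$label))) {
    abort("all records must carry standard labels; run filter_standard_labels()")
  }
  if (is.null(context)) {
    context <- compute_operation_context(
      records, stat = config$context_stat,
      time_points_per_label = config$time_points_per_label,
      sentinel = config$sentinel
    )
  }
  n <- nrow(records)
  det <- detect_onset_and_first_peak(records$waveform)
  seg <- truncate_downsample(records$waveform)
  ctx <- context[match(records$operation_id, context$operation_id), ]
  if (anyNA(ctx$operation_id)) abort("context missing for some operations")
  dur <- ctx$ctx_duration

  blocks <- list()
  lay <- list()
  add <- function(name, m, block) {
    blocks[[length(blocks) + 1]] <<- m
    lay[[length(lay) + 1]] <<- tibble::tibble(feature = colnames(m),
                                              block = block)
  }
  if (config$emg_segment) {
    colnames(seg) <- paste0("emg_", sprintf("%03d", seq_len(125)))
    add("emg", seg, "emg_segment")
  }
  if (config$channel_means) {
    m <- as.matrix(ctx[paste0("ctx_ch_mean_", 1:4)])
    add("chm", m, "channel_means")
  }
  if (config$first_peak) {
    m <- cbind(first_peak_latency =
                 ifelse(is.na(det$first_peak_latency), config$sentinel,
                        det$first_peak_latency))
    add("fp", m, "first_peak")
  }
  if (config$label_time_points) {
    tp_cols <- grep("^ctx_tp_", names(ctx), value = TRUE)
    add("tp", as.matrix(ctx[tp_cols]), "label_time_points")
  }
  if (config$stimulus_fields) {
    m <- cbind(
      stimulation_time_norm = records$stimulation_time / dur,
      stimulation_current = records$stimulation_current,
      amplitude = records$amplitude
    )
    add("stim", m, "stimulus_fields")
  }
  if (config$channel_onehot) {
    m1 <- onehot(records$recording_channel, 1:4)
    colnames(m1) <- paste0("rec_channel_", 1:4)
    m2 <- onehot(records$stimulating_channel, 1:2)
    colnames(m2) <- paste0("stim_channel_", 1:2)
    add("ch1", m1, "channel_onehot")
    add("ch2", m2, "channel_onehot")
  }
  if (config$modality_onehot) {
    m <- onehot(records$modality, c("cIONM", "iIONM"))
    colnames(m) <- c("modality_cIONM", "modality_iIONM")
    add("mod", m, "modality_onehot")
  }
  if (config$extra_context) {
    count_cols <- grep("^ctx_count_", names(ctx), value = TRUE)
    counts <- as.matrix(ctx[count_cols])
    sent <- function(x) ifelse(is.na(x), config$sentinel, x)
    segpp <- apply(seg, 1, function(r) max(r) - min(r))
    segrms <- sqrt(rowMeans(seg^2))
    segpk <- (max.col(abs(seg)) - 1) * 4 * WAVEFORM_DT
    ord <- records |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::group_by(.data$operation_id) |>
      dplyr::arrange(.data$stimulation_time, .by_group = TRUE) |>
      dplyr::mutate(
        .dt_prev = c(0, diff(.data$stimulation_time)),
        .dt_next = c(diff(.data$stimulation_time), 0),
        .frac = (dplyr::row_number() - 1) / max(dplyr::n() - 1, 1)
      ) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$.row)
    chmean_own <- as.matrix(ctx[paste0("ctx_ch_mean_", 1:4)])[
      cbind(seq_len(n), records$recording_channel)]
    # relative time of the record inside each side's labelled block:
    # ((t - first label time of that side) / span of that side's labels),
    # computable for either side hypothesis from the label time points
    t_norm <- records$stimulation_time / dur
    rel_side <- function(side) {
      labs6 <- paste0("ctx_tp_",
                      c("V1", "R1", "S1", "R2", "V2", "S2"), side, "_1")
      tp <- as.matrix(ctx[labs6])
      tp[tp == config$sentinel] <- NA
      lo <- apply(tp, 1, function(r) suppressWarnings(min(r, na.rm = TRUE)))
      hi <- apply(tp, 1, function(r) suppressWarnings(max(r, na.rm = TRUE)))
      ok <- is.finite(lo) & is.finite(hi) & (hi - lo) > 0
      out <- rep(config$sentinel, n)
      out[ok] <- pmin(pmax((t_norm[ok] - lo[ok]) / (hi[ok] - lo[ok]), -1), 2)
      out
    }
    m <- cbind(
      counts,
      device_onset_latency = sent(records$onset_latency),
      device_min_peak_latency = sent(records$min_peak_latency),
      device_max_peak_latency = sent(records$max_peak_latency),
      detected_onset_latency = sent(det$onset_latency),
      segment_peak_to_peak = segpp,
      segment_rms = segrms,
      segment_peak_time = segpk,
      dt_prev_norm = ord$.dt_prev / dur,
      dt_next_norm = ord$.dt_next / dur,
      record_order_fraction = ord$.frac,
      amplitude_rel_opmax = records$amplitude / pmax(ctx$ctx_max_amplitude, 1e-12),
      amplitude_rel_channel = records$amplitude / pmax(chmean_own, 1e-12),
      operation_duration = dur,
      side_block_time_l = rel_side("l"),
      side_block_time_r = rel_side("r")
    )
    add("extra", m, "extra_context")
  }

  x <- do.call(cbind, blocks)
  layout <- dplyr::bind_rows(lay)
  width <- ncol(x)
  if (width < 150 || width > 280) {
    warn(sprintf("feature width %d outside the usual 150-280 range", width))
  }
  onehot_blocks <- c("channel_onehot", "modality_onehot")
  numeric_features <- layout$feature[!layout$block %in% onehot_blocks]

  if (normalize) {
    if (is.null(normalizer)) {
      normalizer <- fit_normalizer(x, numeric_features)
    }
    x <- apply_normalizer(x, normalizer)
  }

  parts <- split_label(records$label)
  y <- list(
    nerve = onehot(parts$nerve, c("V", "R", "S")),
    side = onehot(parts$side, c("l", "r")),
    position = onehot(parts$position, c("1", "2"))
  )
  meta <- tibble::tibble(
    row = seq_len(n),
    operation_id = records$operation_id,
    stimulation_time = records$stimulation_time,
    label = records$label,
    true_label = records[["true_label"]] %||% NA_character_
  )
  structure(
    list(x = x, y = y, labels = records$label, layout = layout,
         normalizer = normalizer, meta = meta, config = config),
    class = "ionm_features"
  )
}

#' @export
print.ionm_features <- function(x, ...) {
  cat(sprintf("<ionm_features> %d records x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$normalizer)) "raw" else "normalized"))
  invisible(x)
}

#' Fit / apply min-max normalization
#'
#' `fit_normalizer()` learns per-feature minimum and range on the supplied
#' matrix (training rows); `apply_normalizer()` rescales a matrix with those
#' frozen parameters, so held-out statistics never leak into the scaling.
#'
#' @param x Feature matrix with column names.
#' @param features Character vector of columns to scale (others untouched).
#' @return `fit_normalizer()`: a tibble with `feature`, `min`, `range`;
#'   `apply_normalizer()`: the rescaled matrix.
#' @export
fit_normalizer <- function(x, features = colnames(x)) {
  features <- intersect(features, colnames(x))
  mins <- apply(x[, features, drop = FALSE], 2, min)
  maxs <- apply(x[, features, drop = FALSE], 2, max)
  tibble::tibble(feature = features, min = mins, range = maxs - mins)
}

#' @rdname fit_normalizer
#' @param normalizer A fitted normalizer tibble.
#' @export
apply_normalizer <- function(x, normalizer) {
  idx <- match(normalizer$feature, colnames(x))
  if (anyNA(idx)) abort("normalizer features not present in matrix")
  rng <- ifelse(normalizer$range == 0, 1, normalizer$range)
  x[, idx] <- sweep(sweep(x[, idx, drop = FALSE], 2, normalizer$min), 2,
                    rng, "/")
  x
}

#' Persist / load a feature set as plain text
#'
#' The matrix and targets go to CSV; the layout, normalizer and feature
#' configuration to a JSON sidecar, so train/test reuse is auditable.
#'
#' @param features An `ionm_features` object.
#' @param prefix Path prefix; writes `<prefix>_x.csv`, `<prefix>_meta.csv`
#'   and `<prefix>_layout.json`.
#' @return `prefix` invisibly; `read_features()` returns the object.
#' @export
write_features <- function(features, prefix) {
  readr::write_csv(tibble::as_tibble(features$x), paste0(prefix, "_x.csv"),
                   progress = FALSE)
  readr::write_csv(features$meta, paste0(prefix, "_meta.csv"),
                   progress = FALSE)
  side <- list(
    layout = features$layout,
    normalizer = features$normalizer,
    config = unclass(features$config)
  )
  jsonlite::write_json(side, paste0(prefix, "_layout.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_features
#' @export
read_features <- function(prefix) {
  x <- as.matrix(readr::read_csv(paste0(prefix, "_x.csv"),
                                 show_col_types = FALSE, progress = FALSE))
  meta <- readr::read_csv(paste0(prefix, "_meta.csv"),
                          show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(paste0(prefix, "_layout.json"),
                              simplifyVector = TRUE)
  cfg <- side$config
  config <- do.call(feature_config, cfg[setdiff(names(cfg), "context_stat")])
  config$context_stat <- cfg$context_stat
  parts <- split_label(meta$label)
  y <- list(
    nerve = onehot(parts$nerve, c("V", "R", "S")),
    side = onehot(parts$side, c("l", "r")),
    position = onehot(parts$position, c("1", "2"))
  )
  normalizer <- if (is.null(side$normalizer)) NULL else
    tibble::as_tibble(side$normalizer)
  structure(
    list(x = x, y = y, labels = meta$label,
         layout = tibble::as_tibble(side$layout),
         normalizer = normalizer, meta = meta, config = config),
    class = "ionm_features"
  )
}
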