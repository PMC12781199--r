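# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# a small mixed corpus: a few continuous and intermittent operations
small_corpus <- function() {
  memo("small_corpus", simulate_corpus(8, seed = 424242))
}

small_features <- function() {
  memo("small_features", {
    corpus <- small_corpus()
    ctx <- compute_operation_context(corpus$records)
    lab <- filter_standard_labels(corpus$records)
    build_feature_matrix(lab, context = ctx, normalize = FALSE)
  })
}

# deliberately small network, enough to learn the high-SNR toy corpus a bit
tiny_config <- function(epochs = 4L, seed = 7L) {
  model_config(
    gru_units = c(6L, 4L), conv_filters = c(4L, 4L), kernel_sizes = c(3L, 3L),
    dense_units = 12L, batch_size = 128L, epochs = epochs, seed = seed
  )
}

tiny_trained_model <- function() {
  memo("tiny_trained_model", {
    f <- small_features()
    plan <- make_split(nrow(f$x), seed = 99)
    train_model(f, plan, tiny_config())
  })
}

tiny_plan <- function() {
  f <- small_features()
  make_split(nrow(f$x), seed = 99)
}

# one labelled record tibble with a deterministic waveform
one_record <- function(label = "V1l", waveform = NULL,
                       operation_id = "opX", time = 1000) {
  tibble::tibble(
    operation_id = operation_id, modality = "cIONM",
    stimulation_time = time, stimulation_current = 1.5,
    amplitude = 500, onset_latency = 2.5, min_peak_latency = 3.5,
    max_peak_latency = 3.0, stimulating_channel = 2L,
    recording_channel = 1L, baseline_flag = "", label = label,
    true_label = label,
    waveform = list(waveform %||% rep(0, 1400))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain one-hot matrix with class columns, for evaluation fixtures
onehot_m <- function(x, levels) {
  m <- matrix(0, length(x), length(levels), dimnames = list(NULL, levels))
  m[cbind(seq_along(x), match(x, levels))] <- 1
  m
}
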