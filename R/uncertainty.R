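# Monte Carlo dropout -------------------------------------------------------

#' Monte Carlo dropout inference
#'
#' Runs up to 30 stochastic forward passes with dropout active (independent
#' masks per pass; batch-norm uses its running statistics), approximating
#' the predictive posterior. Final class probabilities are the average over
#' the sampled class distributions; the raw per-head uncertainty is by
#' default the predictive entropy of that mean distribution (in nats), or
#' the mean per-class variance across samples.
#'
#' @param model A trained `ionm_model` (must carry dropout layers).
#' @param features `ionm_features` or a pre-normalized matrix.
#' @param n_samples Number of posterior samples (1-30 typical).
#' @param seed Seed for the dropout masks; results are deterministic given
#'   the seed.
#' @param statistic `"entropy"` (default) or `"variance"`.
#' @param keep_samples Keep the per-sample probability blocks (memory-heavy).
#' @return An object of class `ionm_posterior`: `mean` (list of per-head
#'   mean probability matrices), `raw` (long tibble: `row`, `head`,
#'   `predicted_class`, `raw_uncertainty`), `n_samples`, `statistic`, and
#'   optionally `samples`.
#' @export
mc_dropout_predict <- function(model, features, n_samples = 30L, seed = 1L,
                               statistic = c("entropy", "variance"),
                               keep_samples = FALSE) {
  statistic <- match.arg(statistic)
  if (n_samples < 1) abort("n_samples must be >= 1")
  rates <- unlist(model$config$dropout)
  if (is.null(rates) || length(rates) == 0) {
    abort("model configuration has no dropout layers; MC dropout needs them")
  }
  x <- if (inherits(features, "ionm_features")) {
    feature_matrix_for(model, features)
  } else {
    features
  }
  xin <- model_inputs(model, x)
  set.seed(seed)
  heads <- c("nerve", "side", "position")
  sums <- NULL
  sumsq <- NULL
  samples <- if (keep_samples) vector("list", n_samples) else NULL
  for (s in seq_len(n_samples)) {
    probs <- nn_forward_chunked(model$params, model$state, xin$seq, xin$ctx,
                                model$config, mode = "mc")
    if (is.null(sums)) {
      sums <- probs
      sumsq <- lapply(probs, function(p) p^2)
    } else {
      for (h in heads) {
        sums[[h]] <- sums[[h]] + probs[[h]]
        sumsq[[h]] <- sumsq[[h]] + probs[[h]]^2
      }
    }
    if (keep_samples) samples[[s]] <- probs
  }
  mean_p <- lapply(sums, function(p) p / n_samples)
  raw <- lapply(heads, function(h) {
    p <- mean_p[[h]]
    u <- if (statistic == "entropy") {
      -rowSums(p * log(pmax(p, 1e-12)))
    } else {
      rowMeans(pmax(sumsq[[h]] / n_samples - p^2, 0))
    }
    cls <- switch(h, nerve = c("V", "R", "S"), side = c("l", "r"),
                  position = c("1", "2"))
    tibble::tibble(row = seq_len(nrow(p)), head = h,
                   predicted_class = cls[max.col(p)], raw_uncertainty = u)
  })
  structure(
    list(mean = mean_p, raw = dplyr::bind_rows(raw),
         n_samples = as.integer(n_samples), statistic = statistic,
         samples = samples),
    class = "ionm_posterior"
  )
}

#' @export
print.ionm_posterior <- function(x, ...) {
  cat(sprintf("<ionm_posterior> %d records, %d MC-dropout samples (%s)\n",
              nrow(x$mean$nerve), x$n_samples, x$statistic))
  invisible(x)
}

# Welford streaming moments --------------------------------------------------

#' Streaming mean and standard deviation (Welford updates)
#'
#' Single-pass, numerically stable running moments: each update touches only
#' the running count, mean and sum of squared deviations, never previous
#' values. `welford_stats()` returns the running mean and the sample
#' standard deviation (`NA` sentinel while fewer than two values have been
#' seen).
#'
#' @param state A state list from `welford_init()` or a previous update.
#' @param value Numeric value(s) to fold in (vectors are folded in order).
#' @return `welford_init()`/`welford_update()`: a state list with `n`,
#'   `mean`, `m2`; `welford_stats()`: a list with `n`, `mean`, `sd`.
#' @export
welford_init <- function() {
  list(n = 0L, mean = 0, m2 = 0)
}

#' @rdname welford_init
#' @export
welford_update <- function(state, value) {
  for (v in value) {
    state$n <- state$n + 1L
    delta <- v - state$mean
    state$mean <- state$mean + delta / state$n
    state$m2 <- state$m2 + delta * (v - state$mean)
  }
  state
}

#' @rdname welford_init
#' @export
welford_stats <- function(state) {
  list(
    n = state$n,
    mean = if (state$n > 0) state$mean else NA_real_,
    sd = if (state$n > 1) sqrt(state$m2 / (state$n - 1)) else NA_real_
  )
}

# Calibration -----------------------------------------------------------------

#' Fit the Gaussian uncertainty-calibration table
#'
#' Streams the raw MC-dropout uncertainties of a random subset of training
#' rows (default 330) through Welford accumulators, one per model branch and
#' predicted class, modelling each empirical training-uncertainty
#' distribution as a Gaussian N(mu, sigma). Cells with fewer than two
#' observations are marked unfitted; cells with zero spread are marked
#' degenerate.
#'
#' @param model A trained `ionm_model`.
#' @param features `ionm_features` for the training corpus.
#' @param rows Training row indices the subset is drawn from (never test
#'   rows).
#' @param subset_size Number of randomly selected signals (default 330).
#' @param n_samples MC-dropout samples per signal.
#' @param seed Seed for subset selection and dropout.
#' @param statistic Raw uncertainty statistic, see [mc_dropout_predict()].
#' @return An object of class `ionm_calibration`: a tibble with `head`,
#'   `class`, `n`, `mu`, `sigma`, `fitted`, `degenerate`.
#' @export
fit_calibration <- function(model, features, rows, subset_size = 330L,
                            n_samples = 30L, seed = 1L,
                            statistic = c("entropy", "variance")) {
  statistic <- match.arg(statistic)
  if (subset_size > length(rows)) {
    abort("subset_size exceeds the number of available training rows")
  }
  set.seed(seed)
  pick <- sample(rows, subset_size)
  x <- if (inherits(features, "ionm_features")) {
    feature_matrix_for(model, features)
  } else {
    features
  }
  post <- mc_dropout_predict(model, x[pick, , drop = FALSE],
                             n_samples = n_samples, seed = seed + 1L,
                             statistic = statistic)
  cls <- list(nerve = c("V", "R", "S"), side = c("l", "r"),
              position = c("1", "2"))
  out <- list()
  for (h in names(cls)) {
    for (cl in cls[[h]]) {
      vals <- post$raw$raw_uncertainty[post$raw$head == h &
                                         post$raw$predicted_class == cl]
      st <- welford_update(welford_init(), vals)
      ws <- welford_stats(st)
      out[[length(out) + 1]] <- tibble::tibble(
        head = h, class = cl, n = ws$n,
        mu = ws$mean, sigma = ws$sd,
        fitted = ws$n >= 2 && !is.na(ws$sd) && ws$sd > 0,
        degenerate = ws$n >= 2 && !is.na(ws$sd) && ws$sd == 0
      )
    }
  }
  structure(
    dplyr::bind_rows(out),
    subset_size = as.integer(subset_size),
    n_samples = as.integer(n_samples),
    statistic = statistic,
    class = c("ionm_calibration", "tbl_df", "tbl", "data.frame")
  )
}

#' Map a raw uncertainty to its calibrated cumulative probability
#'
#' The calibrated uncertainty is the probability that a training-set
#' uncertainty in the same branch/predicted-class cell is less than or equal
#' to the observed value, i.e. the Gaussian CDF value
#' `pnorm((raw - mu) / sigma)`. Values near 1 mean "atypically uncertain
#' relative to training". Unfitted or degenerate cells yield `NA` with a
#' warning (such records are routed to manual review).
#'
#' @param raw Numeric vector of raw uncertainties.
#' @param head Branch name(s): `"nerve"`, `"side"` or `"position"`.
#' @param predicted_class Predicted class per value.
#' @param calibration An [fit_calibration()] table.
#' @return Calibrated values in `[0, 1]` (or `NA` sentinels).
#' @export
calibrate_uncertainty <- function(raw, head, predicted_class, calibration) {
  key <- paste(head, predicted_class)
  ckey <- paste(calibration$head, calibration$class)
  idx <- match(key, ckey)
  if (anyNA(idx)) abort("unknown head/class combination")
  mu <- calibration$mu[idx]
  sigma <- calibration$sigma[idx]
  ok <- calibration$fitted[idx]
  out <- rep(NA_real_, length(raw))
  out[ok] <- pnorm((raw[ok] - mu[ok]) / sigma[ok])
  if (any(!ok)) {
    warn(sprintf(
      "%d value(s) fall in unfitted/degenerate calibration cells; returning NA (manual review)",
      sum(!ok)))
  }
  out
}

#' Calibrate a whole posterior
#'
#' Applies [calibrate_uncertainty()] to every (record, head) raw uncertainty
#' of an [mc_dropout_predict()] result.
#'
#' @param posterior An `ionm_posterior`.
#' @param calibration An `ionm_calibration`.
#' @return The posterior's `raw` tibble with a `calibrated` column.
#' @export
calibrate_posterior <- function(posterior, calibration) {
  raw <- posterior$raw
  raw$calibrated <- calibrate_uncertainty(
    raw$raw_uncertainty, raw$head, raw$predicted_class, calibration)
  raw
}

#' Flag records whose calibrated uncertainty is atypically high
#'
#' A record is flagged for manual review when the calibrated uncertainty of
#' any head exceeds the threshold (records with unfitted-cell `NA`
#' uncertainties are always flagged).
#'
#' @param calibrated Long tibble with `row`, `head`, `calibrated` (e.g. from
#'   [calibrate_posterior()]).
#' @param threshold Value in `[0, 1]`.
#' @return A tibble with `row` and logical `review_flag`.
#' @export
flag_for_review <- function(calibrated, threshold) {
  if (threshold < 0 || threshold > 1) abort("threshold must lie in [0, 1]")
  calibrated |>
    dplyr::group_by(.data$row) |>
    dplyr::summarise(
      review_flag = any(is.na(.data$calibrated) |
                          .data$calibrated > threshold),
      .groups = "drop"
    )
}

#' Save / load a calibration table as JSON
#'
#' @param calibration An `ionm_calibration`.
#' @param path JSON path.
#' @return `path` invisibly; `load_calibration()` returns the table.
#' @export
save_calibration <- function(calibration, path) {
  jsonlite::write_json(
    list(
      subset_size = attr(calibration, "subset_size"),
      n_samples = attr(calibration, "n_samples"),
      statistic = attr(calibration, "statistic"),
      cells = as.data.frame(calibration)
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    tibble::as_tibble(ser$cells),
    subset_size = ser$subset_size,
    n_samples = ser$n_samples,
    statistic = ser$statistic,
    class = c("ionm_calibration", "tbl_df", "tbl", "data.frame")
  )
}
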