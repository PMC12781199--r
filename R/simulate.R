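# Truncated-normal helpers -----------------------------------------------
# Latency profiles are reported in the field as sample mean(sd) of observed,
# range-limited latencies. We therefore parameterize the *truncated*
# distribution by its own moments and solve for the parent normal, so that
# simulated draws reproduce the quoted mean/sd without truncation bias.

truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  d <- (dnorm(al) - dnorm(be)) / z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z - d^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

solve_truncnorm <- function(target_mean, target_sd, a, b) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), a, b)
    (mo[1] - target_mean)^2 + (mo[2] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm <- function(n, mu, sigma, a, b) {
  lo <- pnorm(a, mu, sigma)
  hi <- pnorm(b, mu, sigma)
  qnorm(runif(n, lo, hi), mu, sigma)
}

# Profiles ----------------------------------------------------------------

#' Define the evoked-response profile of a nerve/side combination
#'
#' A profile holds the onset-latency distribution (a truncated normal
#' parameterized by the moments of the truncated draw itself), a log-normal
#' amplitude distribution and the shape parameters of the evoked-response
#' kernel used by [synth_waveform()].
#'
#' @param nerve One of `"V"`, `"R"`, `"S"`.
#' @param side One of `"l"`, `"r"`.
#' @param latency_mean,latency_sd Target mean and sd of the drawn onset
#'   latency in ms.
#' @param latency_min,latency_max Truncation bounds in ms (within `[0, 70]`).
#' @param amplitude_log_mean,amplitude_log_sd Log-normal parameters of the
#'   evoked amplitude in device units (microvolts as stored).
#' @param period Dominant period of the biphasic kernel in ms.
#' @param decay Exponential decay constant of the kernel in ms.
#' @param polarity `+1` or `-1`, sign of the leading phase.
#' @return An object of class `nerve_profile`.
#' @export
nerve_profile <- function(nerve, side, latency_mean, latency_sd,
                          latency_min, latency_max,
                          amplitude_log_mean = log(600),
                          amplitude_log_sd = 0.5,
                          period = 4, decay = 2.5, polarity = 1) {
  stopifnot(nerve %in% c("V", "R", "S"), side %in% c("l", "r"),
            latency_min >= 0, latency_max <= 70,
            latency_mean > latency_min, latency_mean < latency_max,
            latency_sd > 0, period > 0, decay > 0)
  parent <- solve_truncnorm(latency_mean, latency_sd, latency_min, latency_max)
  structure(
    list(
      nerve = nerve, side = side,
      latency_mean = latency_mean, latency_sd = latency_sd,
      latency_min = latency_min, latency_max = latency_max,
      parent_mu = parent$mu, parent_sigma = parent$sigma,
      amplitude_log_mean = amplitude_log_mean,
      amplitude_log_sd = amplitude_log_sd,
      period = period, decay = decay, polarity = polarity
    ),
    class = "nerve_profile"
  )
}

#' Draw onset latencies from a nerve profile
#'
#' Samples from the profile's truncated-normal onset-latency distribution
#' (uses the current RNG state).
#'
#' @param profile A [nerve_profile()].
#' @param n Number of draws.
#' @return Numeric vector of latencies in ms, inside the profile's bounds.
#' @export
draw_latency <- function(profile, n = 1) {
  rtruncnorm(n, profile$parent_mu, profile$parent_sigma,
             profile$latency_min, profile$latency_max)
}

#' Default nerve profiles for the synthetic surgeries
#'
#' The recurrent laryngeal nerve (RLN) profile uses the reported onset
#' latency of 2.5(0.7) ms within 1.1-10 ms, and the right vagal profile
#' 4.2(0.8) ms. The left vagal nerve (longer conduction path) and the
#' external branch of the superior laryngeal nerve (EBSLN, overlapping the
#' RLN latency band) are not quantified in the field the same way; their
#' parameters are documented synthetic conventions.
#'
#' @return A named list of [nerve_profile()] objects keyed `"V.l"`, `"V.r"`,
#'   `"R.l"`, `"R.r"`, `"S.l"`, `"S.r"`.
#' @export
default_nerve_profiles <- function() {
  list(
    R.l = nerve_profile("R", "l", 2.5, 0.7, 1.1, 10, log(700), 0.45,
                        period = 4.0, decay = 2.5),
    R.r = nerve_profile("R", "r", 2.5, 0.7, 1.1, 10, log(700), 0.45,
                        period = 4.0, decay = 2.5),
    V.r = nerve_profile("V", "r", 4.2, 0.8, 2.0, 12, log(600), 0.45,
                        period = 4.6, decay = 3.0),
    V.l = nerve_profile("V", "l", 6.5, 0.9, 3.0, 14, log(600), 0.45,
                        period = 4.6, decay = 3.0),
    S.l = nerve_profile("S", "l", 3.3, 0.8, 1.1, 12, log(280), 0.5,
                        period = 3.2, decay = 2.0, polarity = -1),
    S.r = nerve_profile("S", "r", 3.3, 0.8, 1.1, 12, log(280), 0.5,
                        period = 3.2, decay = 2.0, polarity = -1)
  )
}

# Waveform synthesis ------------------------------------------------------

#' Synthesize one evoked EMG waveform
#'
#' Baseline Gaussian noise with a damped single-cycle biphasic response
#' (a decaying sinusoid) starting exactly at the requested onset latency.
#' The kernel is scaled so its sampled peak-to-peak excursion equals
#' `amplitude`; activity decays to the noise floor well before the end of
#' the 70 ms record, with the dominant peaks inside the first 25 ms.
#' Uses the current RNG state; seed via `set.seed()` or the simulation
#' drivers.
#'
#' @param profile A [nerve_profile()] supplying kernel shape.
#' @param latency Onset latency in ms (in `[0, 70]`).
#' @param amplitude Peak-to-peak amplitude in device units.
#' @param noise_level Standard deviation of the baseline noise.
#' @return Numeric vector of 1400 samples (70 ms at 0.05 ms).
#' @export
synth_waveform <- function(profile, latency, amplitude, noise_level) {
  stopifnot(latency >= 0, latency <= 70)
  t <- (seq_len(WAVEFORM_N) - 1) * WAVEFORM_DT
  s <- t - latency
  k <- numeric(WAVEFORM_N)
  on <- s >= 0
  k[on] <- sin(2 * pi * s[on] / profile$period) * exp(-s[on] / profile$decay)
  pp <- max(k) - min(k)
  wave <- rnorm(WAVEFORM_N, 0, noise_level)
  if (pp > 0 && amplitude != 0) {
    wave <- wave + profile$polarity * amplitude * k / pp
  }
  wave
}

synth_artefact <- function(noise_level) {
  t <- (seq_len(WAVEFORM_N) - 1) * WAVEFORM_DT
  t0 <- runif(1, 3, 45)
  width <- runif(1, 2, 8)
  env <- exp(-((t - t0)^2) / (2 * width^2))
  burst_amp <- exp(runif(1, log(50), log(1500)))
  rnorm(WAVEFORM_N, 0, noise_level) + env * rnorm(WAVEFORM_N, 0, burst_amp)
}

# Scenarios ---------------------------------------------------------------

#' Describe one synthetic surgery
#'
#' A scenario fixes the monitoring modality, the operated sides, the
#' per-side standard stimulation sequence (V1, R1, \[S1\], R2, V2, \[S2\]),
#' how many signals the team stores per label, the density of unlabelled
#' automatic vagal stimulations (continuous monitoring only), noise and
#' artefact levels, and the per-side gain of the four recording channels on
#' the tube electrode.
#'
#' @param modality `"cIONM"` (continuous) or `"iIONM"` (intermittent).
#' @param sides Character subset of `c("l", "r")`.
#' @param include_sln Whether the superior laryngeal nerve is stimulated
#'   (S1/S2 labels emitted).
#' @param signals_per_label Integer range `c(lo, hi)`: number of stored
#'   signals per label, drawn uniformly.
#' @param unlabelled_per_side Number of unlabelled automatic vagal records
#'   per side (continuous monitoring; a device stores far more — this is a
#'   deliberately thinned stream with the same temporal structure).
#' @param duration Operation duration in ms.
#' @param noise_level Baseline noise sd in device units.
#' @param artefact_rate Expected artefact annotations per stored record.
#' @param channel_gains 2x4 numeric matrix (rows `l`, `r`): relative gain of
#'   each recording channel for responses from that side.
#' @param current_range Stimulation current range in mA.
#' @return An object of class `surgery_scenario`.
#' @export
surgery_scenario <- function(modality = c("cIONM", "iIONM"),
                             sides = c("l", "r"),
                             include_sln = modality[1] == "cIONM",
                             signals_per_label = c(1L, 3L),
                             unlabelled_per_side = if (modality[1] == "cIONM") 40L else 0L,
                             duration = 7.2e6,
                             noise_level = 5,
                             artefact_rate = 0.03,
                             channel_gains = default_channel_gains(),
                             current_range = c(1, 2)) {
  modality <- match.arg(modality)
  if (length(sides) == 0) abort("sides_operated must not be empty")
  stopifnot(all(sides %in% c("l", "r")), duration > 0, noise_level > 0,
            artefact_rate >= 0, length(signals_per_label) == 2,
            signals_per_label[1] >= 1,
            signals_per_label[2] >= signals_per_label[1])
  structure(
    list(
      modality = modality, sides = sides, include_sln = include_sln,
      signals_per_label = as.integer(signals_per_label),
      unlabelled_per_side = as.integer(unlabelled_per_side),
      duration = duration, noise_level = noise_level,
      artefact_rate = artefact_rate, channel_gains = channel_gains,
      current_range = current_range
    ),
    class = "surgery_scenario"
  )
}

#' @rdname surgery_scenario
#' @export
default_channel_gains <- function() {
  g <- rbind(
    l = c(1.00, 0.20, 0.25, 0.80),
    r = c(0.20, 1.00, 0.85, 0.25)
  )
  colnames(g) <- paste0("ch", 1:4)
  g
}

# stereotypical relative times (fraction of the side block) of the standard
# per-side sequence; jitter added at simulation time preserves the ordering
LABEL_SEQUENCE_FRACTIONS <- c(
  V1 = 0.04, R1 = 0.16, S1 = 0.27, R2 = 0.70, V2 = 0.83, S2 = 0.93
)

# Operation simulation ----------------------------------------------------

# generate all stimulation events of one operation in vectorized form;
# events is a data frame of (time, nerve, side, label, true_label, stim_ch)
materialize_events <- function(events, scenario, profiles, gains_op) {
  n <- nrow(events)
  wave <- vector("list", n)
  amp <- numeric(n)
  onset <- numeric(n)
  minpk <- numeric(n)
  maxpk <- numeric(n)
  rec_ch <- integer(n)
  for (i in seq_len(n)) {
    prof <- profiles[[paste(events$nerve[i], events$side[i], sep = ".")]]
    latency <- draw_latency(prof)
    base_amp <- rlnorm(1, prof$amplitude_log_mean, prof$amplitude_log_sd)
    ch_amp <- base_amp * gains_op[events$side[i], ] * exp(rnorm(4, 0, 0.05))
    rec_ch[i] <- which.max(ch_amp)
    amp[i] <- ch_amp[rec_ch[i]]
    w <- synth_waveform(prof, latency, amp[i], scenario$noise_level)
    wave[[i]] <- w
    onset[i] <- detect_onset_one(w, 1, 5, 3L)[1]
    minpk[i] <- (which.min(w) - 1) * WAVEFORM_DT
    maxpk[i] <- (which.max(w) - 1) * WAVEFORM_DT
  }
  tibble::tibble(
    stimulation_time = events$time,
    stimulation_current = round(runif(n, scenario$current_range[1],
                                      scenario$current_range[2]), 2),
    amplitude = amp,
    onset_latency = onset,
    min_peak_latency = minpk,
    max_peak_latency = maxpk,
    stimulating_channel = events$stim_ch,
    recording_channel = rec_ch,
    baseline_flag = rep("", n),
    label = events$label,
    true_label = events$true_label,
    waveform = wave
  )
}

#' Simulate one complete surgery
#'
#' Generates every stored EMG record of one operation: the labelled per-side
#' standard sequence (V1, R1, \[S1\], R2, V2, \[S2\]), the unlabelled
#' automatic vagal stream under continuous monitoring, and occasional
#' artefact annotations. The recording channel of each record is the channel
#' with the highest amplitude for the active side, mirroring the device's
#' automatic channel selection. Ground truth (`true_label`) is carried
#' separately from the stored `label`; [inject_label_errors()] corrupts only
#' the latter.
#'
#' @param scenario A [surgery_scenario()].
#' @param profiles Named list of [nerve_profile()]s keyed `"<nerve>.<side>"`.
#' @param seed Integer seed; the same seed reproduces the operation exactly.
#' @param operation_id Identifier stored in the `operation_id` column.
#' @return A records tibble (see [read_operation_csv()] for the schema) with
#'   the extra columns `true_label` (NA for unlabelled/artefact records) and
#'   `label_error` (all `FALSE`), sorted by stimulation time.
#' @export
simulate_operation <- function(scenario, profiles = default_nerve_profiles(),
                               seed = 1L, operation_id = "op0001") {
  set.seed(seed)
  # per-operation electrode placement jitter on channel gains
  gains_op <- scenario$channel_gains * exp(rnorm(8, 0, 0.12))
  sides <- sample(scenario$sides)
  n_sides <- length(sides)
  blocks <- if (n_sides == 2) {
    list(c(0.05, 0.48), c(0.52, 0.95))
  } else {
    list(c(0.10, 0.90))
  }
  seq_labels <- names(LABEL_SEQUENCE_FRACTIONS)
  if (!scenario$include_sln) seq_labels <- setdiff(seq_labels, c("S1", "S2"))

  ev_time <- numeric(0)
  ev_nerve <- character(0)
  ev_side <- character(0)
  ev_label <- character(0)
  ev_truth <- character(0)
  ev_stim <- integer(0)
  for (i in seq_len(n_sides)) {
    side <- sides[i]
    t0 <- blocks[[i]][1] * scenario$duration
    t1 <- blocks[[i]][2] * scenario$duration
    span <- t1 - t0
    for (lab in seq_labels) {
      frac <- LABEL_SEQUENCE_FRACTIONS[[lab]] + runif(1, 0, 0.04)
      n_sig <- sample(seq(scenario$signals_per_label[1],
                          scenario$signals_per_label[2]), 1)
      base <- t0 + frac * span
      times <- base + cumsum(c(0, runif(max(n_sig - 1, 0), 2e3, 1.5e4)))
      nerve <- substr(lab, 1, 1)
      full <- paste0(lab, side)
      stim_ch <- if (nerve == "V" && scenario$modality == "cIONM") 2L else 1L
      ev_time <- c(ev_time, times)
      ev_nerve <- c(ev_nerve, rep(nerve, n_sig))
      ev_side <- c(ev_side, rep(side, n_sig))
      ev_label <- c(ev_label, rep(full, n_sig))
      ev_truth <- c(ev_truth, rep(full, n_sig))
      ev_stim <- c(ev_stim, rep(stim_ch, n_sig))
    }
    if (scenario$unlabelled_per_side > 0) {
      vt <- sort(runif(scenario$unlabelled_per_side, t0, t1))
      ev_time <- c(ev_time, vt)
      ev_nerve <- c(ev_nerve, rep("V", length(vt)))
      ev_side <- c(ev_side, rep(side, length(vt)))
      ev_label <- c(ev_label, rep("", length(vt)))
      ev_truth <- c(ev_truth, rep(NA_character_, length(vt)))
      ev_stim <- c(ev_stim, rep(2L, length(vt)))
    }
  }
  events <- data.frame(time = ev_time, nerve = ev_nerve, side = ev_side,
                       label = ev_label, true_label = ev_truth,
                       stim_ch = ev_stim, stringsAsFactors = FALSE)
  out <- materialize_events(events, scenario, profiles, gains_op)
  n_art <- rbinom(1, nrow(out), min(scenario$artefact_rate, 1))
  if (n_art > 0) {
    art <- vector("list", n_art)
    for (j in seq_len(n_art)) {
      tm <- runif(1, 0.05, 0.95) * scenario$duration
      wave <- synth_artefact(scenario$noise_level)
      art[[j]] <- tibble::tibble(
        stimulation_time = tm,
        stimulation_current = round(runif(1, scenario$current_range[1],
                                          scenario$current_range[2]), 2),
        amplitude = max(wave) - min(wave),
        onset_latency = NA_real_,
        min_peak_latency = (which.min(wave) - 1) * WAVEFORM_DT,
        max_peak_latency = (which.max(wave) - 1) * WAVEFORM_DT,
        stimulating_channel = 1L,
        recording_channel = sample(1:4, 1),
        baseline_flag = "",
        label = "artefact",
        true_label = NA_character_,
        waveform = list(wave)
      )
    }
    out <- dplyr::bind_rows(out, dplyr::bind_rows(art))
  }
  out$operation_id <- operation_id
  out$modality <- scenario$modality
  out$label_error <- FALSE
  out <- dplyr::relocate(out, "operation_id", "modality")
  dplyr::arrange(out, .data$stimulation_time)
}

# Label-error injection ---------------------------------------------------

#' Describe the label-error process
#'
#' Stored labels differ from ground truth in roughly 20% of raw records.
#' Each labelled record is independently corrupted with probability
#' `rate`; the corruption kind is drawn from `kind_weights`: flipping the
#' side, replacing the nerve, flipping the stimulation time point, or
#' replacing the standard label with a free-text annotation. Corrupted
#' standard labels always remain inside the 12-label vocabulary except for
#' annotation substitution.
#'
#' @param rate Probability that a stored label differs from ground truth.
#' @param kind_weights Named non-negative weights for
#'   `c("side", "nerve", "position", "annotation")`.
#' @param annotation_labels Annotations used for the substitution kind.
#' @return An object of class `ionm_error_model`.
#' @export
error_model <- function(rate = 0.20,
                        kind_weights = c(side = 0.35, nerve = 0.30,
                                         position = 0.20, annotation = 0.15),
                        annotation_labels = ionm_label_vocabulary()$annotation) {
  stopifnot(rate >= 0, rate <= 1, all(kind_weights >= 0),
            setequal(names(kind_weights),
                     c("side", "nerve", "position", "annotation")))
  structure(
    list(rate = rate, kind_weights = kind_weights,
         annotation_labels = annotation_labels),
    class = "ionm_error_model"
  )
}

#' Corrupt stored labels according to an error model
#'
#' Applies the error process of [error_model()] to every record whose stored
#' label is standard. Ground truth (`true_label`) is never modified;
#' corrupted records get `label_error = TRUE`.
#'
#' @param records A simulated records tibble (with `true_label`).
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @return `records` with corrupted `label` and updated `label_error`.
#' @export
inject_label_errors <- function(records, model = error_model(), seed = 1L) {
  if (model$rate == 0) return(records)
  set.seed(seed)
  if (is.null(records[["label_error"]])) {
    records$label_error <- rep(FALSE, nrow(records))
  }
  idx <- which(is_standard_label(records$label))
  if (length(idx) == 0) return(records)
  hit <- idx[runif(length(idx)) < model$rate]
  if (length(hit) == 0) return(records)
  w <- model$kind_weights / sum(model$kind_weights)
  kinds <- sample(names(w), length(hit), replace = TRUE, prob = w)
  lab <- records$label
  for (i in seq_along(hit)) {
    r <- hit[i]
    parts <- split_label(lab[r])
    lab[r] <- switch(kinds[i],
      side = join_label(parts$nerve,
                        ifelse(parts$side == "l", "r", "l"), parts$position),
      nerve = join_label(sample(setdiff(c("V", "R", "S"), parts$nerve), 1),
                         parts$side, parts$position),
      position = join_label(parts$nerve, parts$side,
                            ifelse(parts$position == "1", "2", "1")),
      annotation = sample(model$annotation_labels, 1)
    )
  }
  records$label <- lab
  records$label_error[hit] <- TRUE
  records
}

# Corpus ------------------------------------------------------------------

#' Default scenario mix for a synthetic corpus
#'
#' Continuous monitoring dominates thyroid resections; intermittent
#' monitoring is typical of parathyroid procedures with fewer stored signals
#' per side (sometimes fewer than 3). Proportions follow the 1541:508
#' case mix of continuous to intermittent procedures.
#'
#' @return A list of `list(scenario =, prob =)` entries.
#' @export
default_scenario_mix <- function() {
  list(
    list(scenario = surgery_scenario("cIONM"), prob = 1541 / 2049),
    list(scenario = surgery_scenario("iIONM", signals_per_label = c(1L, 2L),
                                     include_sln = FALSE,
                                     duration = 3.6e6),
         prob = 305 / 2049),
    list(scenario = surgery_scenario("iIONM", sides = "l",
                                     signals_per_label = c(1L, 2L),
                                     include_sln = FALSE, duration = 2.7e6),
         prob = 101.5 / 2049),
    list(scenario = surgery_scenario("iIONM", sides = "r",
                                     signals_per_label = c(1L, 2L),
                                     include_sln = FALSE, duration = 2.7e6),
         prob = 101.5 / 2049)
  )
}

#' Simulate a corpus of surgeries
#'
#' Draws `n_operations` scenarios from the mix and simulates each operation
#' with a seed derived from the corpus seed, so any operation is reproducible
#' in isolation. Optionally applies label-error injection to the stored
#' labels of the whole corpus.
#'
#' @param n_operations Number of operations.
#' @param scenario_mix A list as returned by [default_scenario_mix()].
#' @param seed Corpus seed.
#' @param profiles Named list of [nerve_profile()]s.
#' @param error_model An [error_model()] applied to stored labels, or `NULL`
#'   for error-free labels (e.g. a quality-controlled table).
#' @return A list of class `ionm_corpus` with elements `records` (all
#'   operations row-bound) and `manifest` (a tibble of stored-label counts by
#'   modality, plus operation counts).
#' @export
simulate_corpus <- function(n_operations,
                            scenario_mix = default_scenario_mix(),
                            seed = 1L,
                            profiles = default_nerve_profiles(),
                            error_model = NULL) {
  stopifnot(n_operations > 0)
  set.seed(seed)
  probs <- vapply(scenario_mix, `[[`, numeric(1), "prob")
  which_sc <- sample(seq_along(scenario_mix), n_operations,
                     replace = TRUE, prob = probs)
  op_seeds <- sample.int(.Machine$integer.max - 1L, n_operations)
  err_seed <- sample.int(.Machine$integer.max - 1L, 1)
  ops <- vector("list", n_operations)
  for (i in seq_len(n_operations)) {
    ops[[i]] <- simulate_operation(
      scenario_mix[[which_sc[i]]]$scenario, profiles,
      seed = op_seeds[i], operation_id = sprintf("op%05d", i)
    )
  }
  records <- dplyr::bind_rows(ops)
  if (!is.null(error_model)) {
    records <- inject_label_errors(records, error_model, seed = err_seed)
  }
  manifest <- records |>
    dplyr::filter(is_standard_label(.data$label)) |>
    dplyr::count(.data$modality, .data$label, name = "n_records")
  manifest <- dplyr::bind_rows(
    manifest,
    tibble::tibble(
      modality = vapply(scenario_mix, function(s) s$scenario$modality,
                        character(1))[which_sc],
      label = "<operations>"
    ) |>
      dplyr::count(.data$modality, .data$label, name = "n_records")
  )
  structure(list(records = records, manifest = manifest),
            class = "ionm_corpus")
}

#' @export
print.ionm_corpus <- function(x, ...) {
  n_lab <- sum(is_standard_label(x$records$label))
  cat(sprintf(
    "<ionm_corpus> %d records (%d standard-labelled) from %d operations\n",
    nrow(x$records), n_lab, length(unique(x$records$operation_id))
  ))
  invisible(x)
}
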