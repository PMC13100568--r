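#' 1/f background noise by spectral shaping of white noise
#'
#' White Gaussian noise is Fourier transformed, its amplitude spectrum is
#' scaled by `f^(-exponent/2)` (power ~ 1/f^exponent; the DC component is
#' zeroed), transformed back and rescaled to the requested standard
#' deviation. Deterministic given `seed`.
#'
#' @param n number of samples.
#' @param sample_rate Hz.
#' @param exponent aperiodic slope (power ~ 1/f^exponent).
#' @param sd target standard deviation (a.u.).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return Numeric vector of length `n`.
#' @export
noise_1f <- function(n, sample_rate, exponent = 1.0, sd = 1.0, seed = NULL) {
  if (sd == 0 || n == 0) return(numeric(n))
  gen <- function() {
    z <- stats::rnorm(n)
    X <- stats::fft(z)
    f <- c(0, seq_len(n - 1)) * (sample_rate / n)
    f <- pmin(f, sample_rate - f)          # two-sided |frequency|
    scale <- ifelse(f > 0, f^(-exponent / 2), 0)
    x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s == 0) x else x * (sd / s)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Add `waveform` to `signal` so that waveform index `ref_idx` lands on
# signal index `at_idx`; truncates at the boundaries. Returns list(signal,
# truncated).
add_waveform <- function(signal, waveform, at_idx, ref_idx) {
  n <- length(signal)
  start <- at_idx - ref_idx + 1L
  end <- start + length(waveform) - 1L
  ws <- max(1L, 1L - start + 1L)
  we <- length(waveform) - max(0L, end - n)
  truncated <- (start < 1L) || (end > n)
  s0 <- max(1L, start)
  if (ws <= we) {
    idx <- s0:(s0 + (we - ws))
    signal[idx] <- signal[idx] + waveform[ws:we]
  }
  list(signal = signal, truncated = truncated)
}

#' Synthesize a single simulated trial
#'
#' EEG = sum of kernel copies (each trough placed `pre_saccade_lag` before
#' its saccade onset) + sum of control-kernel copies at fixation-control
#' onsets + 1/f noise. Strict linear superposition: components are added
#' independently and never interact. Kernels overlapping the trial
#' boundary are truncated (not wrapped) and flagged in `ground_truth`.
#'
#' @param config an [sim_config()].
#' @param condition condition label (must name an entry of
#'   `config$trains`).
#' @param trial_index 1-based trial index (drives the sub-seed scheme).
#' @param window optional override of `config$epoch_window`.
#' @return An object of class `oculo_sim_trial`: list with `eeg`, `time`,
#'   `saccade_onsets`, `control_onsets`, `condition`, and `ground_truth`
#'   (kernel lag, first-saccade latency, event counts, truncation flags).
#' @export
synthesize_trial <- function(config, condition, trial_index,
                             window = NULL) {
  stopifnot(inherits(config, "oculo_sim_config"))
  trains <- config$trains[[condition]]
  if (is.null(trains)) stop_invalid("unknown condition: ", condition)
  ci <- match(condition, names(config$trains))
  w <- window %||% config$epoch_window
  fs <- config$sample_rate
  n <- round((w[2] - w[1]) * fs)
  time <- w[1] + (seq_len(n) - 1L) / fs

  first <- numeric(0)
  expl <- numeric(0)
  ctrl <- numeric(0)
  if (!is.null(trains$first_saccade)) {
    first <- sample_events(trains$first_saccade, w, origin = 0,
                           seed = derive_seed(config$seed, ci, trial_index, 1))
  }
  if (!is.null(trains$exploratory) && length(first)) {
    expl <- sample_events(trains$exploratory, w, origin = first[1],
                          seed = derive_seed(config$seed, ci, trial_index, 2),
                          taper_origin = 0)
  }
  if (!is.null(trains$fixation_control)) {
    ctrl <- sample_events(trains$fixation_control, w, origin = 0,
                          seed = derive_seed(config$seed, ci, trial_index, 3))
  }
  saccades <- sort(c(first, expl))

  eeg <- numeric(n)
  kern <- config$kernel
  trough_idx <- round(kern$trough_offset * fs)
  truncated <- logical(length(saccades))
  for (i in seq_along(saccades)) {
    at <- round((saccades[i] - kern$pre_saccade_lag - w[1]) * fs) + 1L
    res <- add_waveform(eeg, kern$waveform, at, trough_idx + 1L)
    eeg <- res$signal
    truncated[i] <- res$truncated
  }
  if (length(ctrl) && !is.null(config$control_kernel)) {
    ck <- config$control_kernel
    center_idx <- round((ck$center_offset %||%
                           ((ck$p1_offset + ck$trough_offset) / 2)) * fs)
    sgn <- if (config$control_polarity == "alternate") {
      rep_len(c(1, -1), length(ctrl))
    } else {
      rep_len(1, length(ctrl))
    }
    for (i in seq_along(ctrl)) {
      at <- round((ctrl[i] - w[1]) * fs) + 1L
      res <- add_waveform(eeg, sgn[i] * ck$waveform, at, center_idx + 1L)
      eeg <- res$signal
    }
  }
  eeg <- eeg + noise_1f(n, fs, config$noise_exponent, config$noise_sd,
                        seed = derive_seed(config$seed, ci, trial_index, 4))

  structure(list(
    eeg = eeg, time = time,
    saccade_onsets = saccades, control_onsets = ctrl,
    condition = condition,
    ground_truth = list(pre_saccade_lag = kern$pre_saccade_lag,
                        first_saccade_latency = if (length(first)) first[1] else NA_real_,
                        n_saccades = length(saccades),
                        n_control = length(ctrl),
                        truncated = truncated)
  ), class = "oculo_sim_trial")
}

#' Simulate a full stimulus-locked experiment
#'
#' Runs [synthesize_trial()] for every condition and trial, returning
#' stimulus-aligned epochs plus an event table. Trials are laid out on a
#' virtual session timeline (one epoch length per trial) so that all
#' event onsets are non-negative and refer to a common clock.
#' Reproducible: two calls with the same config yield identical output.
#'
#' @param config an [sim_config()].
#' @return A list with `epochs` (an `oculo_epochs`, channel `"POz"`) and
#'   `events` (data.frame: onset, duration, type, condition, trial_id).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "oculo_sim_config"))
  w <- config$epoch_window
  fs <- config$sample_rate
  trial_dur <- w[2] - w[1]
  n_time <- round(trial_dur * fs)
  conds <- names(config$trains)
  n_total <- config$n_trials * length(conds)

  data <- array(NA_real_, dim = c(n_total, 1L, n_time))
  meta <- data.frame(trial_id = seq_len(n_total),
                     condition = rep(conds, each = config$n_trials),
                     first_saccade_latency = NA_real_,
                     n_saccades = 0L, stringsAsFactors = FALSE)
  ev <- vector("list", n_total)
  row <- 0L
  for (cond in conds) {
    for (tr in seq_len(config$n_trials)) {
      row <- row + 1L
      st <- synthesize_trial(config, cond, tr)
      data[row, 1L, ] <- st$eeg
      lat <- st$ground_truth$first_saccade_latency
      meta$first_saccade_latency[row] <- lat
      meta$n_saccades[row] <- st$ground_truth$n_saccades
      stim_abs <- (row - 1L) * trial_dur - w[1]   # session clock
      ev[[row]] <- data.frame(
        onset = stim_abs + c(0, st$saccade_onsets, st$control_onsets),
        duration = 0,
        type = c("stimulus_on",
                 rep("saccade", length(st$saccade_onsets)),
                 rep("fixation_control", length(st$control_onsets))),
        condition = cond, trial_id = row, stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  time <- w[1] + (seq_len(n_time) - 1L) / fs
  epochs <- new_epochs(data, time, fs, channels = "POz",
                       alignment = "stimulus", meta = meta)
  list(epochs = epochs, events = events)
}
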