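#' EEG recording container
#'
#' @param data numeric matrix `channels x samples` (a.u. standing for uV).
#' @param sample_rate Hz.
#' @param labels channel names (10-20 convention); must be unique and
#'   match the row count.
#' @return An object of class `oculo_eeg`.
#' @export
eeg_recording <- function(data, sample_rate, labels) {
  data <- as.matrix(data)
  if (nrow(data) != length(labels)) stop("label count must equal data row count")
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  structure(list(data = data, sample_rate = sample_rate,
                 labels = as.character(labels)),
            class = "oculo_eeg")
}

#' Gaze recording container
#'
#' @param time uniformly sampled time axis in seconds.
#' @param x,y gaze position in screen pixels (origin top-left, y
#'   downward); `NA` where lost.
#' @param pupil pupil diameter in mm (optional, `NA` allowed).
#' @param loss_mask logical per sample; forced `TRUE` wherever x or y is
#'   missing.
#' @param screen list with `width_px`, `height_px`, `width_cm`,
#'   `distance_cm`.
#' @return An object of class `oculo_gaze`.
#' @export
gaze_recording <- function(time, x, y, pupil = NULL, loss_mask = NULL,
                           screen = default_screen()) {
  n <- length(time)
  stopifnot(length(x) == n, length(y) == n)
  if (n > 1) {
    dt <- diff(time)
    if (any(abs(dt - dt[1]) > 1e-9)) stop("time base not uniform")
    if (any(dt <= 0)) stop("time must be strictly increasing")
  }
  loss_mask <- (loss_mask %||% rep(FALSE, n)) | is.na(x) | is.na(y)
  x[loss_mask] <- NA_real_
  y[loss_mask] <- NA_real_
  structure(list(time = time, x = x, y = y,
                 pupil = pupil %||% rep(NA_real_, n),
                 loss_mask = loss_mask, screen = screen,
                 sample_rate = if (n > 1) 1 / (time[2] - time[1]) else NA_real_),
            class = "oculo_gaze")
}

#' @export
default_screen <- function() {
  list(width_px = 1920, height_px = 1080, width_cm = 53, distance_cm = 70)
}

#' Convert a pixel displacement to degrees of visual angle
#'
#' Derived, never stored: uses the screen physical width and viewing
#' distance.
#'
#' @param px displacement in pixels.
#' @param screen screen geometry list (see [gaze_recording()]).
#' @return Degrees of visual angle.
#' @export
px_to_dva <- function(px, screen = default_screen()) {
  cm <- px * screen$width_cm / screen$width_px
  2 * atan2(cm / 2, screen$distance_cm) * 180 / pi
}

#' Gaze generator configuration
#'
#' @param screen screen geometry.
#' @param fixation_sd_px stationary sd of fixational jitter (pixels).
#' @param pullback per-sample pull fraction of the mean-reverting
#'   fixational walk.
#' @param saccade_duration saccadic step duration in seconds.
#' @param targets matrix of candidate landing offsets from screen centre
#'   (pixels, one row per target), or `NULL` for face-like feature
#'   positions.
#' @param blink_rate blink rate in Hz.
#' @param blink_duration `c(min, max)` blink duration in seconds.
#' @param baseline_dur,baseline_jitter baseline fixation duration (s) and
#'   its uniform jitter half-range.
#' @param viewing_dur stimulus viewing duration (s).
#' @return A list of class `oculo_gaze_config`.
#' @export
gaze_config <- function(screen = default_screen(), fixation_sd_px = 15,
                        pullback = 0.02, saccade_duration = 0.025,
                        targets = NULL, blink_rate = 0.1,
                        blink_duration = c(0.100, 0.300),
                        baseline_dur = 3, baseline_jitter = 0.5,
                        viewing_dur = 2) {
  targets <- targets %||% rbind(c(-100, -80), c(100, -80), c(0, 100),
                                c(0, -40), c(-60, 40), c(60, 40))
  structure(list(screen = screen, fixation_sd_px = fixation_sd_px,
                 pullback = pullback, saccade_duration = saccade_duration,
                 targets = targets, blink_rate = blink_rate,
                 blink_duration = blink_duration,
                 baseline_dur = baseline_dur,
                 baseline_jitter = baseline_jitter,
                 viewing_dur = viewing_dur),
            class = "oculo_gaze_config")
}

#' Task presets for session generation
#'
#' `face`: 3 s (+-0.5 s jitter) baseline fixation, 2 s viewing.
#' `iaps`: 1 s (+-0.5 s) baseline, 1 s picture viewing.
#' `eyes-closed`: 4 s baseline, 6 s task interval, no visual targets.
#'
#' @param name preset name.
#' @return An `oculo_gaze_config`.
#' @export
session_preset <- function(name = c("face", "iaps", "eyes-closed")) {
  name <- match.arg(name)
  switch(name,
    face = gaze_config(baseline_dur = 3, baseline_jitter = 0.5,
                       viewing_dur = 2),
    iaps = gaze_config(baseline_dur = 1, baseline_jitter = 0.5,
                       viewing_dur = 1),
    `eyes-closed` = gaze_config(baseline_dur = 4, baseline_jitter = 0,
                                viewing_dur = 6, blink_rate = 0))
}

# Smooth (cosine-ramp) unit step used for saccadic gaze displacement.
smooth_step <- function(n) (1 - cos(pi * seq_len(n) / n)) / 2

#' Generate a full synthetic session (EEG + gaze + events)
#'
#' Concatenates simulated trials into a continuous recording. Each trial
#' is a jittered baseline fixation interval followed by stimulus viewing;
#' trial conditions alternate through the simulator's condition list.
#' EEG: the simulated oculomotor trace is written to the posterior
#' channels (O1, O2, POz) with per-channel gains; the remaining channels
#' carry independent 1/f noise. Gaze: a mean-reverting fixational random
#' walk around the fixation point, a smooth ~25 ms step toward a randomly
#' chosen target region at each saccade event (with a return step at
#' stimulus offset), and blink-like loss gaps.
#'
#' @param config an [sim_config()].
#' @param gcfg an [gaze_config()] / [session_preset()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param n_trials number of trials in the session (default:
#'   `config$n_trials` per condition, interleaved).
#' @return list with `eeg` (`oculo_eeg`), `gaze` (`oculo_gaze`),
#'   `events` (data.frame: onset_s, duration_s, type, condition,
#'   trial_id).
#' @export
generate_session <- function(config, gcfg = gaze_config(), seed = NULL,
                             n_trials = NULL) {
  stopifnot(inherits(config, "oculo_sim_config"),
            inherits(gcfg, "oculo_gaze_config"))
  seed <- seed %||% config$seed
  fs <- config$sample_rate
  conds <- names(config$trains)
  n_trials <- n_trials %||% (config$n_trials * length(conds))
  trial_conds <- rep_len(conds, n_trials)

  # per-trial timing on the session clock
  bdur <- with_seed(derive_seed(seed, 0, 0, 10), {
    round(fs * stats::runif(n_trials, gcfg$baseline_dur - gcfg$baseline_jitter,
                            gcfg$baseline_dur + gcfg$baseline_jitter)) / fs
  })
  vdur <- gcfg$viewing_dur
  trial_len <- bdur + vdur
  stim_onset <- cumsum(c(0, trial_len[-n_trials])) + bdur
  total <- sum(trial_len)
  n <- round(total * fs)
  time <- (seq_len(n) - 1L) / fs

  # ---- EEG -----------------------------------------------------------
  posterior <- c(O1 = 1.0, O2 = 0.95, POz = 0.9)
  others <- c("Fz", "Cz", "Pz")
  labels <- c(names(posterior), others)
  eeg <- matrix(0, nrow = length(labels), ncol = n)
  events <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    st <- synthesize_trial(config, trial_conds[i], i,
                           window = c(-bdur[i], vdur))
    i0 <- round((stim_onset[i] - bdur[i]) * fs) + 1L
    idx <- i0:(i0 + length(st$eeg) - 1L)
    idx <- idx[idx <= n]
    for (ch in seq_along(posterior)) {
      eeg[ch, idx] <- eeg[ch, idx] + posterior[ch] * st$eeg[seq_along(idx)]
    }
    sacc <- st$saccade_onsets + stim_onset[i]
    ctrl <- st$control_onsets + stim_onset[i]
    events[[i]] <- data.frame(
      onset = c(stim_onset[i], stim_onset[i] + vdur, sacc, ctrl),
      duration = c(vdur, 0, rep(gcfg$saccade_duration, length(sacc)),
                   rep(0, length(ctrl))),
      type = c("stimulus_on", "stimulus_off",
               rep("saccade", length(sacc)),
               rep("fixation_control", length(ctrl))),
      condition = trial_conds[i], trial_id = i, stringsAsFactors = FALSE)
  }
  for (ch in seq_along(others)) {
    eeg[length(posterior) + ch, ] <-
      noise_1f(n, fs, config$noise_exponent, config$noise_sd,
               seed = derive_seed(seed, 0, ch, 11))
  }
  events <- do.call(rbind, events)

  # ---- gaze ----------------------------------------------------------
  scr <- gcfg$screen
  center <- c(scr$width_px / 2, scr$height_px / 2)
  sacc_ev <- events[events$type == "saccade", , drop = FALSE]
  off_ev <- events[events$type == "stimulus_off", , drop = FALSE]
  g <- with_seed(derive_seed(seed, 0, 0, 12), {
    step_sd <- gcfg$fixation_sd_px * sqrt(2 * gcfg$pullback)
    x <- numeric(n); y <- numeric(n)
    anchor <- center
    x[1] <- center[1]; y[1] <- center[2]
    # anchor displacement schedule: each saccade steps to a target,
    # each stimulus offset steps back to centre
    steps <- rbind(
      data.frame(t = sacc_ev$onset,
                 to_center = rep(FALSE, nrow(sacc_ev))),
      data.frame(t = off_ev$onset,
                 to_center = rep(TRUE, nrow(off_ev))))
    steps <- steps[order(steps$t), , drop = FALSE]
    n_step <- max(2L, round(gcfg$saccade_duration * fs))
    ramp <- smooth_step(n_step)
    dx <- numeric(n); dy <- numeric(n)   # deterministic displacement track
    cur <- c(0, 0)                       # anchor offset from centre
    last_target <- 0L
    for (j in seq_len(nrow(steps))) {
      tgt <- if (steps$to_center[j]) {
        last_target <- 0L
        c(0, 0)
      } else {
        # saccades always move: never land on the current target again
        pick <- if (nrow(gcfg$targets) > 1L) {
          sample(setdiff(seq_len(nrow(gcfg$targets)), last_target), 1L)
        } else 1L
        last_target <- pick
        as.numeric(gcfg$targets[pick, ])
      }
      i1 <- round(steps$t[j] * fs) + 1L
      if (i1 > n) next
      seg <- i1:min(n, i1 + n_step - 1L)
      delta <- tgt - cur
      dx[seg] <- dx[seg] + delta[1] * ramp[seq_along(seg)]
      dy[seg] <- dy[seg] + delta[2] * ramp[seq_along(seg)]
      if (i1 + n_step <= n) {
        rest <- (i1 + n_step):n
        dx[rest] <- dx[rest] + delta[1]
        dy[rest] <- dy[rest] + delta[2]
      }
      cur <- tgt
    }
    jx <- numeric(n); jy <- numeric(n)
    ex <- stats::rnorm(n, 0, step_sd); ey <- stats::rnorm(n, 0, step_sd)
    for (i in 2:n) {
      jx[i] <- jx[i - 1] * (1 - gcfg$pullback) + ex[i]
      jy[i] <- jy[i - 1] * (1 - gcfg$pullback) + ey[i]
    }
    # drift-like fixational movement: low-pass the walk (ocular drift has
    # most energy well below the sampling rate), then restore the target sd
    nlp <- 21L
    lp <- rep(1 / nlp, nlp)
    hw <- (nlp - 1L) %/% 2L
    smooth_pad <- function(v) {
      p <- stats::filter(c(rep(v[1], hw), v, rep(v[n], hw)), lp, sides = 2)
      as.numeric(p[(hw + 1):(n + hw)])
    }
    jx <- smooth_pad(jx); jy <- smooth_pad(jy)
    jx <- jx * (gcfg$fixation_sd_px / max(stats::sd(jx), 1e-9))
    jy <- jy * (gcfg$fixation_sd_px / max(stats::sd(jy), 1e-9))
    x <- center[1] + dx + jx
    y <- center[2] + dy + jy
    x <- pmin(pmax(x, 0), scr$width_px)
    y <- pmin(pmax(y, 0), scr$height_px)
    pupil <- 3 + 0.2 * sin(2 * pi * 0.05 * time) + stats::rnorm(n, 0, 0.02)
    # blink-like loss gaps
    lost <- rep(FALSE, n)
    blinks <- NULL
    if (gcfg$blink_rate > 0) {
      nb <- stats::rpois(1, gcfg$blink_rate * total)
      if (nb > 0) {
        bt <- sort(stats::runif(nb, 0, total))
        bd <- stats::runif(nb, gcfg$blink_duration[1], gcfg$blink_duration[2])
        for (j in seq_len(nb)) {
          seg <- round(bt[j] * fs):round((bt[j] + bd[j]) * fs) + 1L
          seg <- seg[seg >= 1 & seg <= n]
          lost[seg] <- TRUE
        }
        blinks <- data.frame(onset = bt, duration = bd,
                             type = "blink", condition = "none",
                             trial_id = NA_integer_,
                             stringsAsFactors = FALSE)
      }
    }
    x[lost] <- NA_real_; y[lost] <- NA_real_; pupil[lost] <- NA_real_
    list(x = x, y = y, pupil = pupil, lost = lost, blinks = blinks)
  })
  if (!is.null(g$blinks)) events <- rbind(events, g$blinks)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  names(events)[1:2] <- c("onset", "duration")

  list(eeg = eeg_recording(eeg, fs, labels),
       gaze = gaze_recording(time, g$x, g$y, g$pupil, g$lost, scr),
       events = events)
}
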