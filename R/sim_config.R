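#' Full parameterization of the generative oculomotor model
#'
#' Houses the saccade-preceding kernel, the optional fixation-control
#' kernel, the per-condition event-train specifications, the 1/f noise
#' parameters, trial counts, the epoch window and the master seed.
#'
#' @param kernel an [make_kernel()] object.
#' @param control_kernel an optional [make_control_kernel()] object.
#' @param trains named list (one entry per condition); each entry is a
#'   named list of [event_train_spec()]s (names `first_saccade`,
#'   `exploratory`, `fixation_control` as applicable).
#' @param noise_exponent 1/f spectral slope (power ~ 1/f^exponent).
#' @param noise_sd standard deviation of the background noise in a.u.
#' @param n_trials trials per condition.
#' @param epoch_window `c(start, end)` seconds relative to stimulus onset;
#'   must contain a pre-stimulus baseline (start < 0 < end).
#' @param sample_rate Hz; must exceed twice the highest analysis
#'   frequency (40 Hz).
#' @param seed master integer seed.
#' @param control_polarity `"fixed"` (same polarity for every control
#'   event; the kernel's zero net area guarantees ERP cancellation) or
#'   `"alternate"` (deterministic even/odd sign alternation).
#' @return An object of class `oculo_sim_config`.
#' @export
sim_config <- function(kernel, control_kernel = NULL, trains,
                       noise_exponent = 1.0, noise_sd = 2.0,
                       n_trials = 1000, epoch_window = c(-2, 2),
                       sample_rate = 250, seed = 1,
                       control_polarity = c("fixed", "alternate")) {
  stopifnot(inherits(kernel, "oculo_kernel"))
  if (!is.null(control_kernel)) stopifnot(inherits(control_kernel, "oculo_kernel"))
  if (!(epoch_window[1] < 0 && 0 < epoch_window[2])) {
    stop_invalid("epoch_window must include a pre-stimulus baseline (start < 0 < end)")
  }
  if (sample_rate <= 2 * 40) {
    stop_invalid("sample_rate must exceed 2 x 40 Hz (highest analysis frequency)")
  }
  if (!is.list(trains) || is.null(names(trains)) || any(names(trains) == "")) {
    stop_invalid("trains must be a named list of conditions")
  }
  for (cond in names(trains)) {
    for (tr in trains[[cond]]) stopifnot(inherits(tr, "oculo_train_spec"))
  }
  structure(list(kernel = kernel, control_kernel = control_kernel,
                 trains = trains, noise_exponent = noise_exponent,
                 noise_sd = noise_sd, n_trials = as.integer(n_trials),
                 epoch_window = epoch_window, sample_rate = sample_rate,
                 seed = as.integer(seed),
                 control_polarity = match.arg(control_polarity)),
            class = "oculo_sim_config")
}

#' Named simulation presets
#'
#' `figS4`: two viewing conditions (high vs low exploration) sharing the
#' same pre-saccadic kernel; the first saccade latency follows a truncated
#' normal centred at 290 ms, exploratory saccades form a tapered renewal
#' train whose rate differs only by `rate_scale` (1.0 vs 0.6). No
#' fixation-control events. `figS5` adds the fixation-control train
#' (mean recurrence 105 ms, i.e. spectral mass near 9.5 Hz) and its
#' zero-mean biphasic control kernel during the pre-stimulus fixation
#' interval.
#'
#' The emulated recording world: 250 Hz sampling, 1/f noise (exponent 1.0,
#' sd 2.0 a.u.), epochs spanning -2..2 s around stimulus onset, trough of
#' the kernel 120 ms before each saccade.
#'
#' @param name `"figS4"` or `"figS5"`.
#' @param n_trials trials per condition (default 1000).
#' @param seed master seed.
#' @param sample_rate Hz.
#' @param noise_sd background noise sd in a.u.
#' @return An `oculo_sim_config`.
#' @export
sim_preset <- function(name = c("figS4", "figS5"), n_trials = 1000, seed = 1,
                       sample_rate = 250, noise_sd = 2.0) {
  name <- match.arg(name)
  kernel <- make_kernel(sample_rate = sample_rate)
  first <- event_train_spec("first_saccade",
                            first_latency = c(0.290, 0.025, 0.150, 0.450))
  expl <- function(rs) event_train_spec("exploratory",
                                        iei = c(0.300, 0.080, 0.120, 0.800),
                                        rate_scale = rs, taper = 0.5)
  trains <- list(
    high = list(first_saccade = first, exploratory = expl(1.0)),
    low  = list(first_saccade = first, exploratory = expl(0.6))
  )
  control_kernel <- NULL
  if (name == "figS5") {
    ctrl <- event_train_spec("fixation_control",
                             iei = c(0.105, 0.015, 0.060, 0.200))
    trains$high$fixation_control <- ctrl
    trains$low$fixation_control <- ctrl
    control_kernel <- make_control_kernel(sample_rate = sample_rate)
  }
  sim_config(kernel = kernel, control_kernel = control_kernel,
             trains = trains, noise_exponent = 1.0, noise_sd = noise_sd,
             n_trials = n_trials, epoch_window = c(-2, 2),
             sample_rate = sample_rate, seed = seed)
}

#' Read a simulation configuration from a JSON file
#'
#' The on-disk format mirrors the [sim_config()] fields as nested
#' key-value sections (units: seconds, Hz, a.u.). Either a full
#' specification or `{"preset": "figS4", ...}` overriding preset fields.
#'
#' @param path JSON file path.
#' @return An `oculo_sim_config`.
#' @export
sim_config_from_file <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$preset)) {
    args <- cfg[setdiff(names(cfg), "preset")]
    return(do.call(sim_preset, c(list(name = cfg$preset), args)))
  }
  kern <- do.call(make_kernel, as.list(cfg$kernel))
  ck <- if (!is.null(cfg$control_kernel)) {
    do.call(make_control_kernel, as.list(cfg$control_kernel))
  }
  trains <- lapply(cfg$trains, function(cond) {
    lapply(cond, function(tr) do.call(event_train_spec, as.list(tr)))
  })
  sim_config(kernel = kern, control_kernel = ck, trains = trains,
             noise_exponent = cfg$noise_exponent %||% 1.0,
             noise_sd = cfg$noise_sd %||% 2.0,
             n_trials = cfg$n_trials %||% 1000,
             epoch_window = cfg$epoch_window %||% c(-2, 2),
             sample_rate = cfg$sample_rate %||% 250,
             seed = cfg$seed %||% 1)
}

#' @export
print.oculo_sim_config <- function(x, ...) {
  cat(sprintf("<oculo_sim_config> %d conditions x %d trials @ %g Hz, window [%g, %g] s, noise 1/f^%g sd %g, seed %d\n",
              length(x$trains), x$n_trials, x$sample_rate,
              x$epoch_window[1], x$epoch_window[2],
              x$noise_exponent, x$noise_sd, x$seed))
  invisible(x)
}
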