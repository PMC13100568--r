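#' Specify an oculomotor event train
#'
#' Three kinds of train drive the simulator: the single first saccade after
#' stimulus onset (`first_saccade`, latency drawn from a truncated normal),
#' the subsequent exploratory saccades (`exploratory`, a renewal process
#' whose inter-event intervals come from a truncated normal, scaled by
#' `1/rate_scale` and by an optional exponential rate taper over viewing
#' time), and the fixation-control events active before stimulus onset
#' (`fixation_control`, a renewal process confined to the fixation
#' interval).
#'
#' @param kind one of `"first_saccade"`, `"exploratory"`,
#'   `"fixation_control"`.
#' @param first_latency numeric `c(mean, sd, lo, hi)` in seconds
#'   (first_saccade kind).
#' @param iei numeric `c(mean, sd, lo, hi)` inter-event-interval
#'   distribution in seconds (renewal kinds).
#' @param rate_scale dimensionless condition multiplier (> 0); intervals
#'   are divided by it.
#' @param taper exponential decay constant (1/s) applied to the
#'   exploratory rate over viewing time; 0 disables.
#' @return An object of class `oculo_train_spec`.
#' @export
event_train_spec <- function(kind = c("first_saccade", "exploratory",
                                      "fixation_control"),
                             first_latency = NULL, iei = NULL,
                             rate_scale = 1, taper = 0) {
  kind <- match.arg(kind)
  check_dist <- function(d, name) {
    if (length(d) != 4L || !all(is.finite(d))) {
      stop_invalid(name, " must be c(mean, sd, lo, hi)")
    }
    if (d[2] < 0) stop_invalid(name, ": sd must be >= 0")
    if (!(0 < d[3] && d[3] < d[4])) stop_invalid(name, ": need 0 < lo < hi")
    d
  }
  if (kind == "first_saccade") {
    first_latency <- check_dist(first_latency, "first_latency")
  } else {
    iei <- check_dist(iei, "iei")
  }
  if (!is.numeric(rate_scale) || rate_scale <= 0) {
    stop_invalid("rate_scale must be > 0")
  }
  if (!is.numeric(taper) || taper < 0) stop_invalid("taper must be >= 0")
  structure(list(kind = kind, first_latency = first_latency, iei = iei,
                 rate_scale = rate_scale, taper = taper),
            class = "oculo_train_spec")
}

#' Sample event onsets from a train specification
#'
#' Deterministic given `seed`. For `first_saccade` a single onset is drawn
#' at `origin + latency`. For `exploratory`, a renewal train is generated
#' from `origin` (normally the first-saccade onset) with intervals
#' `draw / (rate_scale * exp(-taper * (t - taper_origin)))`, so the rate
#' decays exponentially over viewing time. For `fixation_control`, a
#' renewal train runs from the start of the trial window up to (but not
#' including) `origin` (stimulus onset); its starting phase is uniformly
#' randomised so that the train carries no stimulus-locked phase.
#'
#' @param spec an [event_train_spec()].
#' @param trial_window numeric `c(start, end)` in seconds.
#' @param origin anchor in seconds: stimulus onset (first_saccade,
#'   fixation_control) or the first-saccade onset (exploratory).
#' @param seed integer seed.
#' @param taper_origin reference time for the exploratory rate taper
#'   (default `origin`).
#' @return Numeric vector of onsets in seconds (possibly empty).
#' @export
sample_events <- function(spec, trial_window, origin = 0, seed = 1,
                          taper_origin = origin) {
  stopifnot(inherits(spec, "oculo_train_spec"))
  if (trial_window[2] <= trial_window[1]) return(numeric(0))
  with_seed(seed, {
    switch(spec$kind,
      first_saccade = {
        d <- spec$first_latency
        onset <- origin + rtruncnorm(1, d[1], d[2], d[3], d[4])
        onset[in_window(onset, trial_window)]
      },
      exploratory = {
        d <- spec$iei
        # vanishing rate -> unbounded intervals -> empty train
        onsets <- numeric(0)
        t <- origin
        repeat {
          scale <- spec$rate_scale * exp(-spec$taper * max(0, t - taper_origin))
          if (scale <= 0) break
          step <- rtruncnorm(1, d[1], d[2], d[3], d[4]) / scale
          if (!is.finite(step)) break
          t <- t + step
          if (t >= trial_window[2]) break
          if (t >= trial_window[1]) onsets <- c(onsets, t)
          if (length(onsets) > 10000L) break
        }
        onsets
      },
      fixation_control = {
        d <- spec$iei
        hi <- min(origin, trial_window[2])
        lo <- trial_window[1]
        if (hi <= lo) return(numeric(0))
        onsets <- numeric(0)
        # random initial phase decorrelates the train from epoch time zero
        t <- lo + stats::runif(1, 0, rtruncnorm(1, d[1], d[2], d[3], d[4]) /
                                    spec$rate_scale)
        while (t < hi) {
          onsets <- c(onsets, t)
          t <- t + rtruncnorm(1, d[1], d[2], d[3], d[4]) / spec$rate_scale
          if (length(onsets) > 100000L) break
        }
        onsets
      })
  })
}
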