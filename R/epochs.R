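#' Epochs container (trials x channels x time)
#'
#' @param data numeric array `trials x channels x time`.
#' @param time numeric time axis in seconds, relative to the alignment
#'   event; shared by all trials.
#' @param sample_rate Hz.
#' @param channels character channel labels.
#' @param alignment `"stimulus"` or `"saccade_k"`.
#' @param meta data.frame with one row per trial (`condition`,
#'   `trial_id`, optionally `first_saccade_latency`, `bin_index`).
#' @return An object of class `oculo_epochs`.
#' @export
new_epochs <- function(data, time, sample_rate, channels, alignment, meta) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[3] == length(time),
            dim(data)[2] == length(channels),
            dim(data)[1] == nrow(meta))
  structure(list(data = data, time = time, sample_rate = sample_rate,
                 channels = channels, alignment = alignment, meta = meta),
            class = "oculo_epochs")
}

#' @export
print.oculo_epochs <- function(x, ...) {
  cat(sprintf("<oculo_epochs> %d trials x %d channels x %d samples @ %g Hz, %s-locked [%g, %g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sample_rate,
              x$alignment, min(x$time), max(x$time)))
  invisible(x)
}

time_to_index <- function(time, t) which.min(abs(time - t))

#' Segment a continuous recording into epochs
#'
#' Time 0 of every epoch coincides with the sample nearest the alignment
#' event onset (sample-accurate alignment). Trials whose window overlaps
#' a recording edge are dropped with a warning. For stimulus alignment,
#' the per-trial first-saccade latency (within the default 150-300 ms
#' window) is computed from the saccade events and stored in the metadata.
#'
#' @param recording an `oculo_eeg` (see [eeg_recording()]).
#' @param events event table (data.frame with onset, type, condition,
#'   trial_id).
#' @param window `c(start, end)` seconds around the event.
#' @param alignment event type to align to (default `"stimulus_on"`).
#' @return An `oculo_epochs`.
#' @export
epoch <- function(recording, events, window, alignment = "stimulus_on") {
  stopifnot(inherits(recording, "oculo_eeg"))
  fs <- recording$sample_rate
  n <- ncol(recording$data)
  sel <- events[events$type == alignment, , drop = FALSE]
  if (!nrow(sel)) stop("empty-epochs error: no '", alignment, "' events")
  i0 <- round(sel$onset * fs) + 1L
  off <- round(window[1] * fs):(round(window[2] * fs) - 1L)
  ok <- (i0 + off[1]) >= 1L & (i0 + off[length(off)]) <= n
  if (!any(ok)) stop("empty-epochs error: no trial window fits the recording")
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) overlapping recording edges dropped")
  }
  sel <- sel[ok, , drop = FALSE]
  i0 <- i0[ok]
  nchan <- nrow(recording$data)
  data <- array(NA_real_, dim = c(nrow(sel), nchan, length(off)))
  for (i in seq_len(nrow(sel))) {
    data[i, , ] <- recording$data[, i0[i] + off, drop = FALSE]
  }
  sacc <- events[events$type == "saccade", , drop = FALSE]
  lat <- vapply(seq_len(nrow(sel)), function(i) {
    first_saccade_latency(sacc$onset[sacc$trial_id == sel$trial_id[i]],
                          stimulus_onset = sel$onset[i])
  }, numeric(1))
  meta <- data.frame(trial_id = sel$trial_id, condition = sel$condition,
                     first_saccade_latency = lat, stringsAsFactors = FALSE)
  new_epochs(data, off / fs, fs, recording$labels,
             alignment = if (alignment == "stimulus_on") "stimulus" else alignment,
             meta = meta)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window.
#' `-Inf` as the window start means "from the first sample of the epoch".
#'
#' @param epochs an `oculo_epochs`.
#' @param window `c(start, end)` seconds; default `c(-0.170, 0)`.
#' @return The corrected `oculo_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-0.170, 0)) {
  stopifnot(inherits(epochs, "oculo_epochs"))
  idx <- which(epochs$time >= window[1] & epochs$time < window[2])
  if (!length(idx)) stop("baseline window outside epoch")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  # bl (trials x channels) recycles exactly over the trailing time dim
  epochs$data <- epochs$data - as.vector(bl)
  epochs
}

#' Average epochs into an ERP (mean and SEM per channel/time)
#'
#' @param epochs an `oculo_epochs`.
#' @param by `NULL` (grand average) or a metadata column name
#'   (`"condition"`, `"bin_index"`) to average within groups.
#' @param min_n groups smaller than this are flagged.
#' @return An `oculo_erp` (list with `mean`, `sem`, `n_trials`, `time`,
#'   `channels`, `provenance`), or a named list of them when `by` is
#'   given. Empty groups are dropped with a warning.
#' @export
average <- function(epochs, by = NULL, min_n = 10) {
  stopifnot(inherits(epochs, "oculo_epochs"))
  make_erp <- function(rows, label) {
    n <- length(rows)
    if (!n) return(NULL)
    d <- epochs$data[rows, , , drop = FALSE]
    m <- apply(d, c(2, 3), mean)
    s <- apply(d, c(2, 3), stats::sd) / sqrt(n)
    structure(list(mean = m, sem = s, n_trials = n, time = epochs$time,
                   channels = epochs$channels,
                   provenance = list(alignment = epochs$alignment,
                                     group = label,
                                     low_n = n < min_n)),
              class = "oculo_erp")
  }
  if (is.null(by)) return(make_erp(seq_len(nrow(epochs$meta)), "all"))
  g <- epochs$meta[[by]]
  if (is.null(g)) stop("grouping column not present: ", by)
  groups <- sort(unique(g[!is.na(g)]))
  out <- list()
  for (lv in groups) {
    erp <- make_erp(which(!is.na(g) & g == lv), as.character(lv))
    if (is.null(erp)) warning("empty group dropped: ", lv) else {
      out[[as.character(lv)]] <- erp
    }
  }
  out
}

#' @export
print.oculo_erp <- function(x, ...) {
  cat(sprintf("<oculo_erp> %d trials, %d channels, %s-locked, group '%s'\n",
              x$n_trials, length(x$channels), x$provenance$alignment,
              x$provenance$group))
  invisible(x)
}

#' First-saccade latency within a post-stimulus window
#'
#' @param onsets numeric saccade onsets (seconds, same clock as
#'   `stimulus_onset`).
#' @param stimulus_onset stimulus onset in seconds.
#' @param window half-open `[lo, hi)` window in seconds after stimulus
#'   (default `c(0.150, 0.300)`).
#' @return Latency in seconds, or `NA` if no saccade falls in the window.
#' @export
first_saccade_latency <- function(onsets, stimulus_onset = 0,
                                  window = c(0.150, 0.300)) {
  if (inherits(onsets, "oculo_saccades")) onsets <- onsets$onset
  if (is.data.frame(onsets)) onsets <- onsets$onset
  lat <- sort(onsets) - stimulus_onset
  lat <- lat[in_window(lat, window)]
  if (length(lat)) lat[1] else NA_real_
}

#' Bin trials by first-saccade latency
#'
#' Trials whose first-saccade latency falls in the half-open window are
#' ranked and split into `n_bins` near-equal occupancy (quantile) bins;
#' remaining trials are excluded. Occupancies differ by at most 1.
#'
#' @param epochs an `oculo_epochs` whose metadata contains
#'   `first_saccade_latency`.
#' @param n_bins number of latency bins (default 4).
#' @param window latency window `[lo, hi)` in seconds.
#' @return The subsetted `oculo_epochs`, with `bin_index` (1 = earliest)
#'   added to the metadata.
#' @export
bin_by_saccade_latency <- function(epochs, n_bins = 4,
                                   window = c(0.150, 0.300)) {
  stopifnot(inherits(epochs, "oculo_epochs"))
  lat <- epochs$meta$first_saccade_latency
  keep <- which(!is.na(lat) & in_window(lat, window))
  if (length(keep) < n_bins) stop("fewer trials with in-window saccades than bins")
  r <- rank(lat[keep], ties.method = "first")
  bin <- ceiling(r * n_bins / length(keep))
  out <- subset_epochs(epochs, keep)
  out$meta$bin_index <- as.integer(bin)
  out
}

subset_epochs <- function(epochs, rows) {
  new_epochs(epochs$data[rows, , , drop = FALSE], epochs$time,
             epochs$sample_rate, epochs$channels, epochs$alignment,
             epochs$meta[rows, , drop = FALSE])
}

#' Re-align epochs to saccade onset
#'
#' Each trial's time axis is shifted by an integer number of samples so
#' that time 0 coincides with the k-th saccade onset; the time axis is
#' then cropped to the window shared by all included trials. Trials
#' without a k-th saccade onset (NA) are dropped.
#'
#' @param epochs a stimulus-locked `oculo_epochs`.
#' @param saccade_onsets numeric vector (one onset per trial, seconds
#'   relative to stimulus), or `NULL` to use the metadata
#'   `first_saccade_latency` (k = 1).
#' @param k which saccade the supplied onsets refer to (bookkeeping only).
#' @return A saccade-locked `oculo_epochs`.
#' @export
realign_to_saccade <- function(epochs, saccade_onsets = NULL, k = 1) {
  stopifnot(inherits(epochs, "oculo_epochs"))
  onsets <- saccade_onsets %||% epochs$meta$first_saccade_latency
  stopifnot(length(onsets) == nrow(epochs$meta))
  keep <- which(!is.na(onsets))
  if (!length(keep)) stop("no trials with a saccade onset")
  ep <- subset_epochs(epochs, keep)
  fs <- ep$sample_rate
  shift <- round(onsets[keep] * fs)         # saccade sample, stimulus-relative
  n_time <- length(ep$time)
  b <- round(ep$time[1] * fs)               # first sample, stimulus-relative
  # saccade-relative sample numbers q common to all trials:
  # trial i covers q in [b - shift_i, b + n_time - 1 - shift_i]
  q_lo <- b - min(shift)
  q_hi <- b + n_time - 1L - max(shift)
  if (q_lo > q_hi) stop("overlap window empty after re-alignment")
  q <- q_lo:q_hi
  out <- array(NA_real_, dim = c(length(keep), dim(ep$data)[2], length(q)))
  for (i in seq_along(keep)) {
    src <- q + shift[i] - b + 1L
    out[i, , ] <- ep$data[i, , src, drop = FALSE]
  }
  new_epochs(out, q / fs, fs, ep$channels,
             alignment = paste0("saccade_", k), meta = ep$meta)
}

#' Latency of a signed extremum in an ERP window
#'
#' @param erp an `oculo_erp`.
#' @param search_window `c(start, end)` seconds.
#' @param polarity `"negative"` (minimum) or `"positive"` (maximum).
#' @param channels channels to average before the search (default: all).
#' @return Latency in seconds (attribute `flat` set when the signal is
#'   constant over the window; ties break to the earliest sample).
#' @export
component_latency <- function(erp, search_window,
                              polarity = c("negative", "positive"),
                              channels = NULL) {
  stopifnot(inherits(erp, "oculo_erp"))
  polarity <- match.arg(polarity)
  trace <- erp_trace(erp, channels)
  idx <- which(erp$time >= search_window[1] & erp$time <= search_window[2])
  if (!length(idx)) stop("search window outside epoch")
  seg <- trace[idx]
  j <- if (polarity == "negative") which.min(seg) else which.max(seg)
  out <- erp$time[idx[j]]
  attr(out, "flat") <- diff(range(seg)) == 0
  out
}

#' Mean ERP amplitude over a time window
#'
#' The LPP-style summary: the time-average of the (channel-averaged) ERP
#' over `window`.
#'
#' @param erp an `oculo_erp`.
#' @param window `c(start, end)` seconds, default `c(0.400, 1.000)`.
#' @param channels channels to include (default: all).
#' @return A scalar in a.u.
#' @export
window_mean <- function(erp, window = c(0.400, 1.000), channels = NULL) {
  stopifnot(inherits(erp, "oculo_erp"))
  trace <- erp_trace(erp, channels)
  idx <- which(erp$time >= window[1] & erp$time < window[2])
  if (!length(idx)) stop("window outside epoch")
  mean(trace[idx])
}

erp_trace <- function(erp, channels = NULL) {
  rows <- if (is.null(channels)) seq_along(erp$channels) else {
    m <- match(channels, erp$channels)
    if (anyNA(m)) stop("unknown channel(s): ",
                       paste(channels[is.na(m)], collapse = ", "))
    m
  }
  colMeans(erp$mean[rows, , drop = FALSE])
}
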