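#' Time-frequency representation container
#'
#' @param power numeric array `trials x channels x freq x time` (raw
#'   power, a.u.^2) or `1 x channels x freq x time` after averaging.
#' @param freqs frequencies in Hz.
#' @param times window-centre times in seconds.
#' @param channels channel labels.
#' @param sample_rate Hz of the underlying signal.
#' @param units `"raw"`, `"dB"` or `"density"`.
#' @param baseline_window baseline window used for dB conversion, or
#'   `NULL`.
#' @return An object of class `oculo_tfr`.
#' @export
new_tfr <- function(power, freqs, times, channels, sample_rate,
                    units = "raw", baseline_window = NULL) {
  stopifnot(length(dim(power)) == 4L,
            dim(power)[3] == length(freqs),
            dim(power)[4] == length(times))
  structure(list(power = power, freqs = freqs, times = times,
                 channels = channels, sample_rate = sample_rate,
                 units = units, baseline_window = baseline_window),
            class = "oculo_tfr")
}

#' @export
print.oculo_tfr <- function(x, ...) {
  cat(sprintf("<oculo_tfr> %d x %d ch x %d freq (%g-%g Hz) x %d times, units %s\n",
              dim(x$power)[1], dim(x$power)[2], length(x$freqs),
              min(x$freqs), max(x$freqs), length(x$times), x$units))
  invisible(x)
}

#' Hanning-taper sliding-window time-frequency decomposition
#'
#' Power at each (frequency, time) point comes from a Hanning-tapered
#' segment of fixed length centred at that time, stepped across the
#' epoch. With the default 0.5 s window the frequency resolution is 2 Hz
#' (no zero-padding: the grid is set by the window length); requested
#' frequencies must be multiples of `1/window`. Segments are demeaned
#' before tapering so DC offsets do not leak into the lowest bins. Time
#' points whose window would be incomplete are marked missing (`NA`).
#'
#' @param epochs an `oculo_epochs`.
#' @param window taper length in seconds (default 0.5).
#' @param step time step in seconds (default 0.05).
#' @param freqs frequencies in Hz (default `seq(2, 40, by = 2)`).
#' @param keep_trials if `FALSE`, average power over trials (first dim
#'   becomes 1).
#' @return An `oculo_tfr` with raw power.
#' @export
tfr_hanning <- function(epochs, window = 0.5, step = 0.05,
                        freqs = seq(2, 40, by = 2), keep_trials = TRUE) {
  stopifnot(inherits(epochs, "oculo_epochs"))
  fs <- epochs$sample_rate
  n_win <- round(window * fs)
  n_time <- length(epochs$time)
  if (n_win > n_time) stop("window longer than epoch")
  fres <- 1 / window
  bins <- freqs / fres
  if (any(abs(bins - round(bins)) > 1e-9) || any(bins < 1) ||
      any(bins > n_win / 2)) {
    stop("freqs must be multiples of 1/window within (0, Nyquist]")
  }
  bins <- round(bins)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_win - 1) / (n_win - 1))
  pscale <- 2 / (fs * sum(taper^2))   # one-sided PSD scaling

  centers <- seq(epochs$time[1], epochs$time[n_time], by = step)
  half_lo <- floor((n_win - 1) / 2)
  half_hi <- n_win - 1L - half_lo
  # floor, not round: a non-integer step in samples (50 ms at 250 Hz is
  # 12.5) must advance by a fixed pattern so that shifts by whole-sample
  # multiples of the step move the map by whole columns
  c_idx <- as.integer(floor((centers - epochs$time[1]) * fs + 1e-9)) + 1L
  valid <- (c_idx - half_lo) >= 1L & (c_idx + half_hi) <= n_time

  n_trials <- dim(epochs$data)[1]
  n_chan <- dim(epochs$data)[2]
  pw <- array(NA_real_, dim = c(n_trials, n_chan, length(bins),
                                length(centers)))
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)),
                 nrow = n_time)  # time x (trials*channels)
  for (ti in which(valid)) {
    seg <- flat[(c_idx[ti] - half_lo):(c_idx[ti] + half_hi), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    X <- stats::mvfft(seg * taper)
    p <- pscale * abs(X[bins + 1L, , drop = FALSE])^2  # freq x (tr*ch)
    pw[, , , ti] <- aperm(array(p, dim = c(length(bins), n_trials, n_chan)),
                          c(2, 3, 1))
  }
  if (!keep_trials) {
    pw <- array(apply(pw, c(2, 3, 4), mean),
                dim = c(1L, n_chan, length(bins), length(centers)))
  }
  new_tfr(pw, freqs, centers, epochs$channels, fs, units = "raw")
}

#' Decibel change relative to a baseline window
#'
#' Per channel and frequency: `10 * log10(power / P0)` where `P0` is the
#' trial- and time-average of raw power over the baseline window. `-Inf`
#' as the window start means "from the earliest valid time point". Zero
#' baseline power yields `NA` (flagged missing), never infinities.
#'
#' @param tfr an `oculo_tfr` in raw units.
#' @param window baseline window `c(start, end)` seconds, default
#'   `c(-Inf, -0.25)`.
#' @return An `oculo_tfr` in dB.
#' @export
db_baseline <- function(tfr, window = c(-Inf, -0.25)) {
  stopifnot(inherits(tfr, "oculo_tfr"))
  if (tfr$units != "raw") stop("db_baseline expects raw power")
  lo <- if (is.infinite(window[1])) min(tfr$times) else window[1]
  tsel <- which(tfr$times >= lo & tfr$times <= window[2])
  # keep only time points with valid (non-missing) power
  tsel <- tsel[vapply(tsel, function(j) any(is.finite(tfr$power[, , , j])),
                      logical(1))]
  if (!length(tsel)) stop("baseline window has no valid time point")
  p0 <- apply(tfr$power[, , , tsel, drop = FALSE], c(2, 3), mean,
              na.rm = TRUE)  # channels x freq
  out <- tfr$power
  for (ch in seq_len(dim(out)[2])) {
    for (fi in seq_len(dim(out)[3])) {
      denom <- p0[ch, fi]
      out[, ch, fi, ] <- if (is.na(denom) || denom <= 0) {
        NA_real_
      } else {
        10 * log10(tfr$power[, ch, fi, ] / denom)
      }
    }
  }
  new_tfr(out, tfr$freqs, tfr$times, tfr$channels, tfr$sample_rate,
          units = "dB", baseline_window = c(lo, window[2]))
}

#' Simplified aperiodic (1/f) removal from a power spectrum
#'
#' Fits `log10(power) ~ a - b * log10(f)` by least squares over the
#' frequency axis, excluding a configurable alpha-band notch from the
#' fit, and returns the periodic residual (log10 units). A deliberately
#' simplified stand-in for full spectral parameterization: it captures
#' the aperiodic trend well enough to expose narrow-band structure.
#'
#' @param freqs frequencies in Hz (>= 5 usable bins).
#' @param power numeric vector (or trials x freq matrix) of raw power;
#'   non-positive bins are excluded from the fit.
#' @param notch frequency band excluded from the fit (default
#'   `c(8, 13)`).
#' @return list with `freqs`, `residual` (same shape as `power`,
#'   log10-power minus fit), `fitted` (log10), `offset`, `slope`.
#' @export
remove_aperiodic <- function(freqs, power, notch = c(8, 13)) {
  vec <- is.null(dim(power))
  pm <- if (vec) matrix(power, nrow = 1) else as.matrix(power)
  stopifnot(ncol(pm) == length(freqs))
  if (length(freqs) < 5) stop("need at least 5 frequency bins")
  lf <- log10(freqs)
  out_res <- matrix(NA_real_, nrow(pm), ncol(pm))
  offsets <- slopes <- numeric(nrow(pm))
  fitted <- matrix(NA_real_, nrow(pm), ncol(pm))
  for (i in seq_len(nrow(pm))) {
    p <- pm[i, ]
    ok <- is.finite(p) & p > 0
    fit_sel <- ok & !(freqs >= notch[1] & freqs <= notch[2])
    if (sum(fit_sel) < 2) stop("too few bins outside the notch to fit")
    co <- stats::lsfit(lf[fit_sel], log10(p[fit_sel]))$coefficients
    offsets[i] <- co[1]
    slopes[i] <- -co[2]
    fitted[i, ] <- co[1] + co[2] * lf
    out_res[i, ok] <- log10(p[ok]) - fitted[i, ok]
  }
  list(freqs = freqs,
       residual = if (vec) out_res[1, ] else out_res,
       fitted = if (vec) fitted[1, ] else fitted,
       offset = if (vec) offsets[1] else offsets,
       slope = if (vec) slopes[1] else slopes)
}

#' Band power time series
#'
#' Mean power over the frequency bins inside `band` (inclusive) and the
#' stated channels.
#'
#' @param tfr an `oculo_tfr`.
#' @param band `c(lo, hi)` Hz, default the 8-12 Hz posterior alpha band.
#' @param channels channel labels (default all).
#' @return Matrix `trials x time` (or vector if a single trial/average).
#' @export
band_power <- function(tfr, band = c(8, 12), channels = NULL) {
  stopifnot(inherits(tfr, "oculo_tfr"))
  fsel <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(fsel)) stop("empty band: no frequency bins in range")
  csel <- if (is.null(channels)) seq_along(tfr$channels) else {
    match(channels, tfr$channels)
  }
  if (anyNA(csel)) stop("unknown channel(s)")
  sub <- tfr$power[, csel, fsel, , drop = FALSE]
  out <- apply(sub, c(1, 4), mean)
  if (nrow(out) == 1) out[1, ] else out
}
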