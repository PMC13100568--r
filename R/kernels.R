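#' Construct a pre-saccadic P1-N170-like kernel
#'
#' The generative model places a fixed biphasic waveform before every
#' saccade: a positive (P1-like) Gaussian bump followed, `p1_to_trough`
#' seconds later, by a deeper negative (N170-like) Gaussian trough. The
#' trough precedes saccade onset by `pre_saccade_lag` seconds when the
#' kernel is placed by [synthesize_trial()].
#'
#' Default parameters are chosen so that (i) the waveform has exactly one
#' global minimum, (ii) the P1-peak-to-trough duration is on the order of
#' the ~100 ms width of the empirical P1-N170 complex, and (iii) the
#' kernel's net time-integral is positive, so that temporally overlapping
#' copies at high saccade rates superpose into a positive sustained (LPP-like)
#' component rather than a negative one.
#'
#' @param p1_amp amplitude (a.u., >= 0) of the positive bump.
#' @param n170_amp amplitude (a.u., < 0) of the negative bump.
#' @param p1_sigma,n170_sigma Gaussian widths in seconds (> 0).
#' @param p1_to_trough separation between bump centres in seconds.
#' @param pre_saccade_lag seconds by which the trough precedes saccade
#'   onset (> 0).
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `oculo_kernel`: list with `sample_rate`,
#'   `time` (s, from waveform start), `waveform` (a.u.), `trough_offset`
#'   (s from start to the most negative sample), `p1_offset` (s to the
#'   most positive sample), `pre_saccade_lag`, and `params`.
#' @examples
#' k <- make_kernel()
#' k$trough_offset - k$p1_offset   # ~ p1_to_trough
#' @export
make_kernel <- function(p1_amp = 1.1, n170_amp = -1.5,
                        p1_sigma = 0.030, n170_sigma = 0.013,
                        p1_to_trough = 0.080, pre_saccade_lag = 0.120,
                        sample_rate = 250) {
  for (nm in c("p1_amp", "n170_amp", "p1_sigma", "n170_sigma",
               "p1_to_trough", "pre_saccade_lag", "sample_rate")) {
    assert_finite_scalar(get(nm), nm)
  }
  if (p1_amp < 0) stop_invalid("p1_amp must be >= 0 (positive bump)")
  if (n170_amp >= 0) stop_invalid("n170_amp must be < 0 (negative bump)")
  if (p1_sigma <= 0 || n170_sigma <= 0) stop_invalid("sigmas must be > 0")
  if (p1_to_trough <= 0) stop_invalid("p1_to_trough must be > 0")
  if (pre_saccade_lag <= 0) stop_invalid("pre_saccade_lag must be > 0")

  pad <- 4
  t_p1 <- pad * p1_sigma
  t_n170 <- t_p1 + p1_to_trough
  t_end <- t_n170 + pad * n170_sigma
  n <- max(2L, ceiling(t_end * sample_rate) + 1L)
  time <- (seq_len(n) - 1L) / sample_rate
  waveform <- p1_amp * exp(-(time - t_p1)^2 / (2 * p1_sigma^2)) +
    n170_amp * exp(-(time - t_n170)^2 / (2 * n170_sigma^2))

  structure(list(
    sample_rate = sample_rate,
    time = time,
    waveform = waveform,
    trough_offset = time[which.min(waveform)],
    p1_offset = time[which.max(waveform)],
    pre_saccade_lag = pre_saccade_lag,
    params = list(p1_amp = p1_amp, n170_amp = n170_amp,
                  p1_sigma = p1_sigma, n170_sigma = n170_sigma,
                  p1_to_trough = p1_to_trough)
  ), class = "oculo_kernel")
}

#' Construct a small zero-mean biphasic fixation-control kernel
#'
#' Fixation is modelled as an actively maintained state: miniature,
#' directionally balanced corrective signals recur roughly every 100 ms.
#' Each event contributes this small biphasic deflection. The two lobes
#' have equal amplitude and width, so the kernel's net time-integral is
#' exactly zero: the stimulus-locked average of a train of such events
#' cancels, while their regular recurrence still carries spectral power
#' near 1/IEI (and the kernel itself is band-pass around
#' `1 / (2 * lobe_separation)`).
#'
#' @param amp lobe amplitude in a.u. (> 0).
#' @param sigma lobe width in seconds.
#' @param lobe_separation centre-to-centre separation of the positive and
#'   negative lobes in seconds (default 0.05 s: band-pass around 10 Hz).
#' @param sample_rate sampling rate in Hz.
#' @return An `oculo_kernel` whose `center_offset` field gives the
#'   placement reference (midpoint between the lobes).
#' @export
make_control_kernel <- function(amp = 0.4, sigma = 0.012,
                                lobe_separation = 0.050, sample_rate = 250) {
  k <- make_kernel(p1_amp = amp, n170_amp = -amp,
                   p1_sigma = sigma, n170_sigma = sigma,
                   p1_to_trough = lobe_separation,
                   pre_saccade_lag = lobe_separation, # unused for control
                   sample_rate = sample_rate)
  # the off-grid lobe centres leave a ~1e-5 discrete residual; remove it so
  # the ERP-cancellation contract is exact
  k$waveform <- k$waveform - mean(k$waveform)
  k$center_offset <- (k$p1_offset + k$trough_offset) / 2
  k
}

#' Duration from the P1 half-maximum rise to the trough
#'
#' A summary of the width of the biphasic complex: the time from the first
#' upward crossing of half the waveform maximum to the global minimum.
#'
#' @param kernel an `oculo_kernel`.
#' @return Duration in seconds.
#' @export
kernel_halfmax_to_trough <- function(kernel) {
  stopifnot(inherits(kernel, "oculo_kernel"))
  w <- kernel$waveform
  half <- max(w) / 2
  i <- which(w >= half)[1]
  kernel$trough_offset - kernel$time[i]
}

#' @export
print.oculo_kernel <- function(x, ...) {
  cat(sprintf(
    "<oculo_kernel> %d samples @ %g Hz | peak %+0.3f @ %.3f s | trough %+0.3f @ %.3f s | lag %.3f s\n",
    length(x$waveform), x$sample_rate, max(x$waveform), x$p1_offset,
    min(x$waveform), x$trough_offset, x$pre_saccade_lag))
  invisible(x)
}
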