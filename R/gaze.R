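#' Instantaneous eye velocity
#'
#' Gaze position is smoothed with a centred moving-average window (100 ms
#' by default), then differentiated (central differences scaled by the
#' sampling rate); the velocity is the Euclidean norm of the horizontal
#' and vertical derivatives, in px/s. Lost samples propagate as missing.
#'
#' @param gaze an `oculo_gaze`.
#' @param smooth_window moving-average length in seconds (>= 2 samples).
#' @return Numeric vector of absolute velocities (px/s), `NA` where
#'   undefined. Attribute `range_corrected` holds a min-max `[0, 1]`
#'   view (a.u.).
#' @export
eye_velocity <- function(gaze, smooth_window = 0.100) {
  stopifnot(inherits(gaze, "oculo_gaze"))
  fs <- gaze$sample_rate
  w <- max(2L, round(smooth_window * fs))
  if (w %% 2L == 0L) w <- w + 1L  # centred window
  sm <- function(v) as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  x <- sm(gaze$x)
  y <- sm(gaze$y)
  grad <- function(v) {
    n <- length(v)
    g <- c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
    g * fs
  }
  v <- sqrt(grad(x)^2 + grad(y)^2)
  fin <- v[is.finite(v)]
  rc <- if (length(fin) && diff(range(fin)) > 0) {
    (v - min(fin)) / diff(range(fin))
  } else {
    v * NA
  }
  attr(v, "range_corrected") <- rc
  # temporal support of the centred estimator: a velocity transient starts
  # this many samples before the underlying position change
  attr(v, "support_samples") <- (w - 1L) %/% 2L + 1L
  v
}

# Separable, mass-preserving Gaussian smoothing with reflected boundaries.
gauss_smooth2d <- function(mat, sigma, radius = ceiling(4 * sigma)) {
  if (sigma <= 0) return(mat)
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) { # along rows (first dim), reflecting pad
    n <- nrow(m)
    pad <- rbind(m[radius:1, , drop = FALSE], m,
                 m[n:(n - radius + 1), , drop = FALSE])
    out <- stats::filter(pad, k, sides = 2)
    out[(radius + 1):(radius + n), , drop = FALSE]
  }
  m <- smooth1(mat)
  t(smooth1(t(m)))
}

#' Gaze-density map over a fixed screen grid
#'
#' Non-lost samples within the half-open time window are binned into a
#' 1000 x 1000 grid spanning the full screen (rectangular bins when the
#' screen is not square), then smoothed with a mass-preserving Gaussian
#' filter (sigma in bins). The unsmoothed grid sums to the number of
#' included samples; smoothing conserves total mass (reflected
#' boundaries).
#'
#' @param gaze an `oculo_gaze`.
#' @param window `c(t0, t1)` seconds.
#' @param grid `c(nx, ny)` bin counts.
#' @param sigma Gaussian smoothing sigma in bins (0 disables).
#' @return An object of class `oculo_density`: list with `grid`
#'   (ny x nx, rows = vertical bins), `x_edges`, `y_edges`, `window`,
#'   `smoothing_sigma`, `n_samples`.
#' @export
gaze_density <- function(gaze, window = NULL,
                         grid = c(1000, 1000), sigma = 5) {
  stopifnot(inherits(gaze, "oculo_gaze"))
  # half-open [t0, t1); the default covers every sample
  window <- window %||% c(gaze$time[1],
                          gaze$time[length(gaze$time)] + 1 / gaze$sample_rate)
  sel <- in_window(gaze$time, window) & !gaze$loss_mask
  if (!any(sel)) stop("empty-map error: zero usable samples in window")
  x <- gaze$x[sel]
  y <- gaze$y[sel]
  x_edges <- seq(0, gaze$screen$width_px, length.out = grid[1] + 1L)
  y_edges <- seq(0, gaze$screen$height_px, length.out = grid[2] + 1L)
  ix <- pmin(pmax(findInterval(x, x_edges, rightmost.closed = TRUE), 1L), grid[1])
  iy <- pmin(pmax(findInterval(y, y_edges, rightmost.closed = TRUE), 1L), grid[2])
  counts <- matrix(0, nrow = grid[2], ncol = grid[1])
  tab <- table(factor(iy, levels = seq_len(grid[2])),
               factor(ix, levels = seq_len(grid[1])))
  counts[] <- as.numeric(tab)
  sm <- gauss_smooth2d(counts, sigma)
  structure(list(grid = sm, counts = counts,
                 x_edges = x_edges, y_edges = y_edges,
                 window = window, smoothing_sigma = sigma,
                 n_samples = sum(sel)),
            class = "oculo_density")
}

#' View a gaze-density map as a TFR-like container
#'
#' Horizontal position plays the role of the "time" axis and vertical
#' position that of the "frequency" axis, so the cluster-permutation
#' machinery consumes density maps unchanged.
#'
#' @param density an `oculo_density`.
#' @return An `oculo_tfr` with `power` of dim `1 x 1 x ny x nx`.
#' @export
as_tfr <- function(density) {
  stopifnot(inherits(density, "oculo_density"))
  ny <- nrow(density$grid); nx <- ncol(density$grid)
  power <- array(density$grid, dim = c(1L, 1L, ny, nx))
  xc <- (density$x_edges[-1] + density$x_edges[-(nx + 1)]) / 2
  yc <- (density$y_edges[-1] + density$y_edges[-(ny + 1)]) / 2
  new_tfr(power, freqs = yc, times = xc, channels = "gaze",
          sample_rate = NA_real_, units = "density")
}

#' Gaze dispersion per trial, z-scored across a trial collection
#'
#' Per trial window: drop lost samples, samples within the screen-border
#' margin, and samples following an inter-sample displacement larger than
#' `jump_reject` of the screen extent; dispersion_raw is then
#' `sqrt(var(x) + var(y))`. Raw values are z-scored across the supplied
#' collection of trials. Trials with fewer than 2 usable samples are
#' dropped (dispersion undefined) and flagged.
#'
#' @param gaze an `oculo_gaze`.
#' @param windows data.frame with columns `t0`, `t1` (seconds, one row
#'   per trial) and optionally `trial_id`.
#' @param border_margin fraction of each screen dimension treated as
#'   border (default 0.05).
#' @param jump_reject displacement threshold as a fraction of the screen
#'   extent (default 0.20).
#' @return data.frame with `trial_id`, `dispersion_raw`, `dispersion_z`,
#'   `n_used`, `n_lost`, `n_border`, `n_jump`, `usable`.
#' @export
gaze_dispersion <- function(gaze, windows, border_margin = 0.05,
                            jump_reject = 0.20) {
  stopifnot(inherits(gaze, "oculo_gaze"))
  scr <- gaze$screen
  extent <- sqrt(scr$width_px^2 + scr$height_px^2)
  bx <- border_margin * scr$width_px
  by <- border_margin * scr$height_px
  res <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- which(in_window(gaze$time, c(windows$t0[i], windows$t1[i])))
    x <- gaze$x[sel]; y <- gaze$y[sel]
    lost <- gaze$loss_mask[sel]
    border <- !lost & (x < bx | x > scr$width_px - bx |
                         y < by | y > scr$height_px - by)
    disp <- c(0, sqrt(diff(x)^2 + diff(y)^2))
    jump <- !lost & !border & !is.na(disp) & disp > jump_reject * extent
    ok <- !lost & !border & !jump
    data.frame(
      trial_id = if (!is.null(windows$trial_id)) windows$trial_id[i] else i,
      dispersion_raw = if (sum(ok) >= 2) {
        sqrt(stats::var(x[ok]) + stats::var(y[ok]))
      } else NA_real_,
      n_used = sum(ok), n_lost = sum(lost), n_border = sum(border),
      n_jump = sum(jump), usable = sum(ok) >= 2)
  })
  out <- do.call(rbind, res)
  m <- mean(out$dispersion_raw, na.rm = TRUE)
  s <- stats::sd(out$dispersion_raw, na.rm = TRUE)
  out$dispersion_z <- if (is.finite(s) && s > 0) {
    (out$dispersion_raw - m) / s
  } else {
    out$dispersion_raw * 0
  }
  out
}

#' Detect saccades from an eye-velocity series
#'
#' Adaptive threshold rule: velocity must exceed
#' `median + k * MAD` of the baseline velocity for at least
#' `min_duration`; events separated by less than `merge_gap` are merged.
#' Onsets are refined by walking back from the threshold crossing while
#' the velocity stays above `median + onset_k * MAD`. Amplitude and
#' direction come from pre-/post-event fixation centroids.
#'
#' @param velocity numeric velocity series (px/s), e.g. from
#'   [eye_velocity()] with a short smoothing window.
#' @param gaze the matching `oculo_gaze`.
#' @param threshold_rule list with `k` (default 6), `onset_k` (default
#'   1), `min_duration` (s, default 0.012), `merge_gap` (s, default
#'   0.020), `baseline_window` (`c(t0, t1)` or `NULL` for the whole
#'   trace), or `threshold` (absolute px/s, overriding the MAD rule).
#' @return data.frame of class `oculo_saccades`: `onset`, `offset`,
#'   `amplitude` (px), `amplitude_dva`, `direction` (radians, screen
#'   coords, in (-pi, pi]), `peak_velocity` (px/s). Empty when nothing
#'   exceeds threshold.
#' @export
detect_saccades <- function(velocity, gaze, threshold_rule = list()) {
  stopifnot(inherits(gaze, "oculo_gaze"))
  fs <- gaze$sample_rate
  tr <- utils::modifyList(list(k = 6, onset_k = 1, min_duration = 0.012,
                               merge_gap = 0.020, baseline_window = NULL,
                               threshold = NULL, support_samples = NULL),
                          threshold_rule)
  bsel <- if (is.null(tr$baseline_window)) rep(TRUE, length(velocity)) else {
    in_window(gaze$time, tr$baseline_window)
  }
  base <- velocity[bsel & !is.na(velocity)]
  med <- stats::median(base)
  md <- stats::mad(base)
  thr <- tr$threshold %||% (med + tr$k * md)
  low <- med + tr$onset_k * md

  above <- !is.na(velocity) & velocity > thr
  if (!any(above)) return(empty_saccades())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < merge_gap
  gap <- round(tr$merge_gap * fs)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] < gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  min_len <- max(1L, round(tr$min_duration * fs))
  merged <- merged[(merged$end - merged$start + 1L) >= min_len, , drop = FALSE]
  if (!nrow(merged)) return(empty_saccades())

  n <- length(velocity)
  win <- max(1L, round(0.050 * fs))
  # centred velocity estimators widen a transient symmetrically; undo the
  # leading-edge spread when locating onsets/offsets
  supp <- tr$support_samples %||% attr(velocity, "support_samples") %||% 0L
  out <- lapply(seq_len(nrow(merged)), function(i) {
    s <- merged$start[i]; e <- merged$end[i]
    while (s > 1 && !is.na(velocity[s - 1]) && velocity[s - 1] > low) s <- s - 1L
    while (e < n && !is.na(velocity[e + 1]) && velocity[e + 1] > low) e <- e + 1L
    pre <- max(1L, s - win):max(1L, s - 1L)
    post <- min(n, e + 1L):min(n, e + win)
    s <- s + supp
    e <- max(e - supp, s)
    cx0 <- mean(gaze$x[pre], na.rm = TRUE); cy0 <- mean(gaze$y[pre], na.rm = TRUE)
    cx1 <- mean(gaze$x[post], na.rm = TRUE); cy1 <- mean(gaze$y[post], na.rm = TRUE)
    amp <- sqrt((cx1 - cx0)^2 + (cy1 - cy0)^2)
    data.frame(onset = gaze$time[s], offset = gaze$time[e],
               amplitude = amp, amplitude_dva = px_to_dva(amp, gaze$screen),
               direction = atan2(cy1 - cy0, cx1 - cx0),
               peak_velocity = max(velocity[s:e], na.rm = TRUE))
  })
  structure(do.call(rbind, out), class = c("oculo_saccades", "data.frame"))
}

empty_saccades <- function() {
  structure(data.frame(onset = numeric(0), offset = numeric(0),
                       amplitude = numeric(0), amplitude_dva = numeric(0),
                       direction = numeric(0), peak_velocity = numeric(0)),
            class = c("oculo_saccades", "data.frame"))
}
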