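test_that("velocity of constant position is zero; lost samples propagate", {
  g <- flat_gaze(500)
  v <- eye_velocity(g)
  # interior is exactly zero; edge samples (incomplete windows) are NA
  expect_true(all(abs(v[20:480]) < 1e-9))
  expect_true(all(is.na(v[1:5])))
  g2 <- gaze_recording(g$time, ifelse(seq_len(500) %in% 200:210, NA, g$x),
                       g$y, screen = g$screen)
  v2 <- eye_velocity(g2, smooth_window = 0.02)
  expect_true(all(is.na(v2[200:210])))
  g3 <- gaze_recording(g$time, rep(NA_real_, 500), rep(NA_real_, 500),
                       screen = g$screen)
  expect_true(all(is.na(eye_velocity(g3))))
})

test_that("linear ramp recovers the analytic velocity", {
  fs <- 250
  t <- (0:999) / fs
  vtrue <- 120
  g <- gaze_recording(t, 100 + vtrue * t, rep(400, 1000))
  v <- eye_velocity(g, smooth_window = 0.1)
  interior <- 30:970
  expect_equal(v[interior], rep(vtrue, length(interior)), tolerance = 1e-6)
})

test_that("a step displacement yields one pulse peaking at the step midpoint", {
  fs <- 250
  n <- 1000
  x <- c(rep(500, 600), rep(700, 400))
  g <- gaze_recording((0:(n - 1)) / fs, x, rep(400, n))
  v <- eye_velocity(g, smooth_window = 0.008)
  # step between samples 600 and 601 -> midpoint 600.5
  expect_lte(abs(which.max(v) - 600.5), 1)
  expect_lt(sum(v > max(v, na.rm = TRUE) / 2, na.rm = TRUE), 15)
})

test_that("velocity is translation invariant and scales with the time axis", {
  fs <- 250
  t <- (0:499) / fs
  x <- 500 + cumsum(rnorm(500, 0, 2))
  y <- 400 + cumsum(rnorm(500, 0, 2))
  g1 <- gaze_recording(t, x, y)
  g2 <- gaze_recording(t, x + 123, y - 77)
  expect_equal(as.numeric(eye_velocity(g1)), as.numeric(eye_velocity(g2)))
  # doubling the sampling rate of the same sample sequence doubles velocity
  g3 <- gaze_recording(t / 2, x, y)
  expect_equal(as.numeric(eye_velocity(g3, smooth_window = 0.05)),
               2 * as.numeric(eye_velocity(g1, smooth_window = 0.1)))
})

test_that("density maps bin, conserve mass, and respect symmetry", {
  g <- flat_gaze(250)
  d <- gaze_density(g, sigma = 0)
  expect_equal(sum(d$counts), 250)
  expect_equal(sum(d$counts > 0), 1L)
  expect_equal(max(d$counts), 250)

  # two equal clusters -> equal smoothed mass in each half
  n <- 400
  x <- c(rep(400, n / 2), rep(1520, n / 2))
  y <- rep(540, n)
  g2 <- gaze_recording((0:(n - 1)) / 250, x, y)
  d2 <- gaze_density(g2, sigma = 5)
  expect_equal(sum(d2$grid), n, tolerance = 1e-6)     # mass conservation
  left <- sum(d2$grid[, 1:500])
  right <- sum(d2$grid[, 501:1000])
  expect_equal(left, right, tolerance = 1e-6)

  # window partition additivity on unsmoothed counts
  da <- gaze_density(g2, window = c(0, 0.5), sigma = 0)
  db <- gaze_density(g2, window = c(0.5, 1.0), sigma = 0)
  dc <- gaze_density(g2, window = c(0, 1.0), sigma = 0)
  expect_equal(da$counts + db$counts, dc$counts)

  expect_error(gaze_density(flat_gaze(10), window = c(100, 101)),
               "empty-map")
})

test_that("density maps expose a TFR-shaped view", {
  d <- gaze_density(flat_gaze(100), sigma = 2)
  tf <- as_tfr(d)
  expect_s3_class(tf, "oculo_tfr")
  expect_equal(dim(tf$power), c(1L, 1L, 1000L, 1000L))
  expect_equal(sum(tf$power), d$n_samples, tolerance = 1e-6)
})

test_that("dispersion matches the variance oracle and its invariances", {
  # constant gaze -> raw dispersion 0
  g0 <- flat_gaze(300)
  d0 <- gaze_dispersion(g0, data.frame(t0 = 0, t1 = 1))
  expect_equal(d0$dispersion_raw, 0)

  set.seed(42)
  n <- 1000
  s <- 12
  x <- rnorm(n, 960, s)
  y <- rnorm(n, 540, s)
  g <- gaze_recording((0:(n - 1)) / 250, x, y)
  d <- gaze_dispersion(g, data.frame(t0 = 0, t1 = 4))
  expect_equal(d$dispersion_raw, s * sqrt(2), tolerance = 0.05)
  # translation invariance and linear scaling (pre z-score)
  g_t <- gaze_recording(g$time, x + 50, y - 30)
  expect_equal(gaze_dispersion(g_t, data.frame(t0 = 0, t1 = 4))$dispersion_raw,
               d$dispersion_raw)
  g_s <- gaze_recording(g$time, 960 + 2 * (x - 960), 540 + 2 * (y - 540))
  expect_equal(gaze_dispersion(g_s, data.frame(t0 = 0, t1 = 4))$dispersion_raw,
               2 * d$dispersion_raw, tolerance = 1e-9)
})

test_that("dispersion exclusions count lost, border and jump samples", {
  scr <- default_screen()
  n <- 200
  x <- rep(960, n)
  y <- rep(540, n)
  x[10:14] <- NA            # lost
  x[20:24] <- 10            # inside the 5% border margin (96 px)
  x[30] <- 1500             # single-sample jump > 20% of the extent
  g <- gaze_recording((0:(n - 1)) / 250, x, y, screen = scr)
  d <- gaze_dispersion(g, data.frame(t0 = 0, t1 = 1))
  expect_equal(d$n_lost, 5L)
  expect_equal(d$n_border, 5L)
  expect_gte(d$n_jump, 1L)
  # too few usable samples -> trial dropped, flagged
  g2 <- flat_gaze(3)
  g2$loss_mask[1:2] <- TRUE
  g2$x[1:2] <- NA
  d2 <- gaze_dispersion(g2, data.frame(t0 = 0, t1 = 1))
  expect_false(d2$usable)
  expect_true(is.na(d2$dispersion_raw))
})

test_that("z-scoring is applied across the trial collection", {
  set.seed(1)
  n <- 3000
  x <- rnorm(n, 960, rep(c(5, 10, 20), each = 1000))
  y <- rnorm(n, 540, rep(c(5, 10, 20), each = 1000))
  g <- gaze_recording((0:(n - 1)) / 250, x, y)
  w <- data.frame(t0 = c(0, 4, 8), t1 = c(4, 8, 12))
  d <- gaze_dispersion(g, w)
  expect_equal(mean(d$dispersion_z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(d$dispersion_z), 1, tolerance = 1e-9)
  expect_true(all(diff(d$dispersion_z) > 0))
})

test_that("saccade detection: empty on quiet traces, exact on a clean step", {
  g <- flat_gaze(1000)
  v <- eye_velocity(g, 0.012)
  expect_equal(nrow(detect_saccades(v, g,
                                    threshold_rule = list(threshold = 500))),
               0L)

  fs <- 250
  n <- 2000
  onset_idx <- 1001L
  ramp <- oculoscope:::smooth_step(6)
  dx <- c(rep(0, onset_idx - 1L), 200 * ramp,
          rep(200, n - onset_idx + 1L - 6L))
  set.seed(3)
  x <- 800 + dx + rnorm(n, 0, 0.5)
  g2 <- gaze_recording((0:(n - 1)) / fs, x, rep(400, n))
  v2 <- eye_velocity(g2, 0.012)
  sc <- detect_saccades(v2, g2)
  expect_equal(nrow(sc), 1L)
  expect_lte(abs(sc$onset - (onset_idx - 1) / fs), 1 / fs + 1e-9)
  expect_equal(sc$amplitude, 200, tolerance = 0.02)
  expect_equal(sc$direction, 0, tolerance = 0.05)
})

test_that("detection recovers generator ground truth on synthetic sessions", {
  cfg <- sim_preset("figS4", n_trials = 20, seed = 13, noise_sd = 1)
  ses <- generate_session(cfg, session_preset("face"), seed = 13,
                          n_trials = 40)
  v <- eye_velocity(ses$gaze, 0.012)
  sc <- detect_saccades(v, ses$gaze)
  gt <- ses$events[ses$events$type == "saccade", ]
  err <- vapply(gt$onset, function(o) min(abs(sc$onset - o)), numeric(1))
  expect_gt(mean(err <= 2 / 250), 0.85)           # hit rate within 2 samples
  expect_lte(stats::median(err), 1 / 250 + 1e-9)  # typical error <= 1 sample
})

test_that("ground-truth first-saccade latencies follow the configured law", {
  spec <- event_train_spec("first_saccade",
                           first_latency = c(0.29, 0.025, 0.15, 0.45))
  lat <- vapply(1:1000, function(s) sample_events(spec, c(-2, 2), seed = s),
                numeric(1))
  ks <- stats::ks.test(lat, function(q) {
    oculoscope:::ptruncnorm(q, 0.29, 0.025, 0.15, 0.45)
  })
  expect_gt(ks$p.value, 0.05)
})

test_that("first-saccade latency windowing is half-open and earliest-first", {
  expect_true(is.na(first_saccade_latency(0.149)))
  expect_equal(first_saccade_latency(c(0.25, 0.2)), 0.2)
  expect_true(is.na(first_saccade_latency(0.3)))       # hi edge excluded
  expect_equal(first_saccade_latency(0.150), 0.150)    # lo edge included
  expect_equal(first_saccade_latency(c(5.18, 5.4), stimulus_onset = 5), 0.18)
})
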