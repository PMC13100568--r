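test_that("epoching is sample-accurate and drops edge trials", {
  fs <- 250
  dat <- matrix(seq_len(2 * 2500), nrow = 2, byrow = TRUE)
  eeg <- eeg_recording(dat, fs, c("O1", "O2"))
  ev <- data.frame(onset = c(2.0, 9.9), duration = 0,
                   type = "stimulus_on", condition = c("a", "b"),
                   trial_id = 1:2)
  expect_warning(ep <- epoch(eeg, ev, c(-0.5, 1)), "dropped")
  expect_equal(dim(ep$data)[1], 1L)
  i0 <- which(ep$time == 0)
  expect_equal(ep$data[1, 1, i0], dat[1, round(2.0 * fs) + 1])
  expect_error(epoch(eeg, ev[0, ], c(-0.5, 1)), "empty-epochs")
})

test_that("baseline correction subtracts exactly the baseline mean", {
  mat <- matrix(7, nrow = 3, ncol = 250)
  ep <- matrix_epochs(mat)
  out <- baseline_correct(ep, c(-0.5, 0))
  expect_true(all(out$data == 0))
  # adding a constant changes nothing after correction
  ep2 <- matrix_epochs(mat + 3.3)
  expect_equal(baseline_correct(ep2, c(-0.5, 0))$data, out$data)
  # known baseline mean m: output = input - m
  set.seed(2)
  m2 <- matrix(rnorm(3 * 250), nrow = 3)
  ep3 <- matrix_epochs(m2)
  bl <- rowMeans(m2[, ep3$time >= -0.5 & ep3$time < 0])
  out3 <- baseline_correct(ep3, c(-0.5, 0))
  expect_equal(out3$data[, 1, ], m2 - bl, tolerance = 1e-12)
  expect_error(baseline_correct(ep3, c(5, 6)), "outside")
})

test_that("averaging returns exact means and SEMs", {
  mat <- rbind(sin(1:100), sin(1:100))
  ep <- matrix_epochs(mat)
  erp <- average(ep)
  expect_equal(as.numeric(erp$mean), sin(1:100))
  expect_true(all(erp$sem == 0))
  a <- rnorm(50); b <- rnorm(50)
  ep2 <- matrix_epochs(rbind(a, b))
  erp2 <- average(ep2)
  expect_equal(as.numeric(erp2$mean), (a + b) / 2)
  expect_equal(as.numeric(erp2$sem), apply(rbind(a, b), 2, sd) / sqrt(2))
  # grouping drops empty groups with a warning, flags small ones
  ep2$meta$condition <- c("x", "y")
  byc <- average(ep2, by = "condition", min_n = 5)
  expect_named(byc, c("x", "y"))
  expect_true(byc$x$provenance$low_n)
})

test_that("latency binning uses rank quantiles with near-equal occupancy", {
  ep <- matrix_epochs(matrix(0, 4, 50))
  ep$meta$first_saccade_latency <- c(0.16, 0.20, 0.24, 0.28)
  b2 <- bin_by_saccade_latency(ep, n_bins = 2)
  expect_equal(b2$meta$bin_index[order(b2$meta$first_saccade_latency)],
               c(1L, 1L, 2L, 2L))
  set.seed(9)
  n <- 103
  ep2 <- matrix_epochs(matrix(0, n, 50))
  ep2$meta$first_saccade_latency <- runif(n, 0.15, 0.2999)
  b4 <- bin_by_saccade_latency(ep2, n_bins = 4)
  occ <- table(b4$meta$bin_index)
  expect_lte(diff(range(occ)), 1)
  # out-of-window trials are excluded
  ep2$meta$first_saccade_latency[1:10] <- 0.35
  expect_equal(nrow(bin_by_saccade_latency(ep2, 4)$meta), n - 10L)
  ep3 <- matrix_epochs(matrix(0, 3, 50))
  ep3$meta$first_saccade_latency <- c(0.2, 0.2, NA)
  expect_error(bin_by_saccade_latency(ep3, 4), "fewer trials")
})

test_that("re-alignment shifts the axis exactly", {
  # all saccades at the same latency: realigned = stimulus-locked shifted
  fs <- 250
  mat <- matrix(rnorm(3 * 500), nrow = 3)
  ep <- matrix_epochs(mat, t0 = -1)
  lat <- rep(0.2, 3)
  re <- realign_to_saccade(ep, lat)
  # equal shifts: no cropping, the whole axis moves by the latency
  expect_equal(re$time, ep$time - 0.2)
  expect_equal(re$data, ep$data)
})

test_that("re-alignment recovers the kernel lag on noiseless trials", {
  cfg <- sim_preset("figS4", n_trials = 60, seed = 17, noise_sd = 0)
  sim <- simulate_experiment(cfg)
  re <- realign_to_saccade(sim$epochs,
                           sim$epochs$meta$first_saccade_latency)
  erp <- average(re)
  trough <- component_latency(erp, c(-0.2, -0.05), "negative")
  expect_equal(as.numeric(trough), -0.120, tolerance = 1 / 250 + 1e-9)
})

test_that("binning and averaging commute with trial permutation", {
  cfg <- sim_preset("figS4", n_trials = 30, seed = 19, noise_sd = 0.5)
  sim <- simulate_experiment(cfg)
  ep <- sim$epochs
  perm <- sample(nrow(ep$meta))
  ep_p <- oculoscope:::subset_epochs(ep, perm)
  b1 <- average(bin_by_saccade_latency(ep, 3), by = "bin_index", min_n = 2)
  b2 <- average(bin_by_saccade_latency(ep_p, 3), by = "bin_index", min_n = 2)
  for (k in names(b1)) expect_equal(b1[[k]]$mean, b2[[k]]$mean)
})

test_that("component latency and window means behave as specified", {
  fs <- 250
  t <- seq(-0.2, 0.8, by = 1 / fs)
  trace <- -exp(-(t - 0.17)^2 / (2 * 0.02^2))
  ep <- matrix_epochs(matrix(trace, 1), t0 = -0.2)
  erp <- average(ep)
  lat <- component_latency(erp, c(0, 0.4), "negative")
  expect_lte(abs(as.numeric(lat) - 0.17), 1 / fs)
  expect_false(attr(lat, "flat"))
  # flat signal: earliest sample wins, flagged
  epf <- matrix_epochs(matrix(1, 1, length(t)), t0 = -0.2)
  latf <- component_latency(average(epf), c(0, 0.4), "negative")
  expect_equal(as.numeric(latf), min(t[t >= 0]))
  expect_true(attr(latf, "flat"))
  # window mean of a constant is that constant
  expect_equal(window_mean(average(epf), c(0.4, 0.8)), 1)
})

test_that("stimulus-locked trough sits near mean latency minus lag", {
  cfg <- sim_preset("figS4", n_trials = 300, seed = 23, noise_sd = 0)
  sim <- simulate_experiment(cfg)
  erp <- average(baseline_correct(sim$epochs))
  trough <- component_latency(erp, c(0.1, 0.25), "negative")
  mean_lat <- mean(sim$epochs$meta$first_saccade_latency, na.rm = TRUE)
  # the P1 falling slope drags the smeared trough a few ms past mean - lag
  expect_lte(abs(as.numeric(trough) - (mean_lat - 0.120)), 0.008)
})
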