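test_that("without saccades gaze stays inside the fixational jitter radius", {
  cfg <- no_event_config(noise_sd = 0.5)
  gcfg <- gaze_config(blink_rate = 0)
  ses <- generate_session(cfg, gcfg, seed = 2, n_trials = 5)
  cx <- gcfg$screen$width_px / 2
  cy <- gcfg$screen$height_px / 2
  expect_lt(max(abs(ses$gaze$x - cx)), 8 * gcfg$fixation_sd_px)
  expect_lt(max(abs(ses$gaze$y - cy)), 8 * gcfg$fixation_sd_px)
})

test_that("a 200 px saccadic step displaces the post-step gaze by ~200 px", {
  cfg <- single_saccade_config(latency = 0.3, window = c(-1, 1.5))
  gcfg <- gaze_config(targets = matrix(c(200, 0), nrow = 1), blink_rate = 0,
                      viewing_dur = 1.5, baseline_dur = 2,
                      baseline_jitter = 0)
  ses <- generate_session(cfg, gcfg, seed = 4, n_trials = 1)
  stim <- ses$events$onset[ses$events$type == "stimulus_on"][1]
  sacc <- ses$events$onset[ses$events$type == "saccade"][1]
  post <- ses$gaze$time > sacc + 0.1 & ses$gaze$time < sacc + 0.6
  cx <- gcfg$screen$width_px / 2
  expect_equal(mean(ses$gaze$x[post]) - cx, 200, tolerance = 0.15)
  expect_lt(abs(mean(ses$gaze$y[post]) - gcfg$screen$height_px / 2), 30)
})

test_that("face-preset baseline durations fall in the jitter range", {
  cfg <- sim_preset("figS4", n_trials = 20, seed = 3, noise_sd = 0.5)
  ses <- generate_session(cfg, session_preset("face"), seed = 6,
                          n_trials = 20)
  stim <- ses$events[ses$events$type == "stimulus_on", ]
  offs <- ses$events[ses$events$type == "stimulus_off", ]
  baselines <- c(stim$onset[1], stim$onset[-1] - offs$onset[-nrow(offs)])
  expect_true(all(baselines >= 2.5 - 1e-9 & baselines <= 3.5 + 1e-9))
})

test_that("write/read round-trips a generated session", {
  cfg <- sim_preset("figS5", n_trials = 3, seed = 1, noise_sd = 1)
  ses <- generate_session(cfg, session_preset("face"), seed = 1,
                          n_trials = 6)
  d <- withr::local_tempdir()
  write_session(d, ses$eeg, ses$gaze, ses$events)
  r <- read_session(d)
  expect_identical(r$eeg$labels, ses$eeg$labels)
  expect_equal(r$eeg$data, ses$eeg$data, tolerance = 1e-6)
  expect_equal(r$gaze$x, ses$gaze$x, tolerance = 1e-6)
  expect_equal(r$gaze$pupil, ses$gaze$pupil, tolerance = 1e-6)
  expect_identical(r$gaze$loss_mask, ses$gaze$loss_mask)
  expect_identical(r$events$type, ses$events$type)
  expect_identical(r$events$trial_id, ses$events$trial_id)
  expect_equal(r$events$onset, ses$events$onset, tolerance = 1e-6)
  expect_equal(r$gaze$screen, ses$gaze$screen)
  # loss gaps encode as blank coordinates
  lines <- readLines(file.path(d, "gaze.tsv"))
  body <- lines[!grepl("^#", lines)][-1]
  lost_rows <- which(ses$gaze$loss_mask)
  if (length(lost_rows)) {
    f <- strsplit(body[lost_rows[1]], "\t")[[1]]
    expect_identical(f[2], "")
    expect_identical(f[5], "1")
  }
})

test_that("re-epoching after a round-trip yields identical epochs", {
  cfg <- sim_preset("figS4", n_trials = 3, seed = 8, noise_sd = 1)
  ses <- generate_session(cfg, session_preset("face"), seed = 8,
                          n_trials = 6)
  d <- withr::local_tempdir()
  write_session(d, ses$eeg, ses$gaze, ses$events)
  r <- read_session(d)
  e1 <- epoch(ses$eeg, ses$events, c(-0.5, 1))
  e2 <- epoch(r$eeg, r$events, c(-0.5, 1))
  expect_equal(e1$data, e2$data, tolerance = 1e-6)
  expect_identical(e1$meta$condition, e2$meta$condition)
  # gaze and EEG share one clock and length
  expect_lte(abs(length(ses$gaze$time) - ncol(ses$eeg$data)), 1L)
})

test_that("empty event tables round-trip as header-only files", {
  ev <- data.frame(onset = numeric(0), duration = numeric(0),
                   type = character(0), condition = character(0),
                   trial_id = integer(0))
  eeg <- eeg_recording(matrix(rnorm(20), 2), 250, c("O1", "O2"))
  gz <- flat_gaze(10)
  d <- withr::local_tempdir()
  write_session(d, eeg, gz, ev)
  expect_length(readLines(file.path(d, "events.tsv")), 1L)
  r <- read_session(d)
  expect_equal(nrow(r$events), 0L)
})

test_that("malformed files raise format errors naming file and line", {
  eeg <- eeg_recording(matrix(rnorm(20), 2), 250, c("O1", "O2"))
  gz <- flat_gaze(10)
  ev <- data.frame(onset = 0.1, duration = 0, type = "saccade",
                   condition = "a", trial_id = 1L)
  d <- withr::local_tempdir()
  write_session(d, eeg, gz, ev)
  # corrupt the EEG header
  p <- file.path(d, "eeg.tsv")
  lines <- readLines(p)
  writeLines(c("bogus_header", lines[-1]), p)
  expect_error(read_session(d), "eeg.tsv \\(line 1\\)")
  writeLines(lines, p)
  # unknown event type, with its line number
  pe <- file.path(d, "events.tsv")
  writeLines(c(readLines(pe), "0.5\t0\twarp\ta\t1"), pe)
  expect_error(read_session(d), "events.tsv \\(line 3\\).*warp")
  # rejected before writing, too
  bad <- ev
  bad$type <- "warp"
  expect_error(write_session(d, eeg, gz, bad), "unknown event type")
})
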