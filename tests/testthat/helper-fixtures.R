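# Shared fixture builders. Everything is generated in code; no stored data.

# A config whose only event is a single saccade at a fixed latency.
single_saccade_config <- function(latency = 0.3, noise_sd = 0, n_trials = 1,
                                  window = c(-0.5, 1), seed = 1) {
  sim_config(
    kernel = make_kernel(),
    trains = list(solo = list(
      first_saccade = event_train_spec(
        "first_saccade",
        first_latency = c(latency, 0, latency - 0.01, latency + 0.01)))),
    noise_sd = noise_sd, n_trials = n_trials,
    epoch_window = window, seed = seed)
}

# A config that produces no events at all (latency support outside window).
no_event_config <- function(noise_sd = 0, window = c(-0.5, 1), seed = 1) {
  sim_config(
    kernel = make_kernel(),
    trains = list(none = list(
      first_saccade = event_train_spec("first_saccade",
                                       first_latency = c(50, 0, 49, 51)))),
    noise_sd = noise_sd, n_trials = 1, epoch_window = window, seed = seed)
}

# Minimal single-channel epochs object from a trials x time matrix.
matrix_epochs <- function(mat, fs = 250, t0 = -0.5, condition = "a") {
  n_tr <- nrow(mat)
  arr <- array(mat, dim = c(n_tr, 1L, ncol(mat)))
  new_epochs(arr, t0 + (seq_len(ncol(mat)) - 1L) / fs, fs, "POz", "stimulus",
             data.frame(trial_id = seq_len(n_tr), condition = condition,
                        first_saccade_latency = NA_real_))
}

with_seed_local <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Constant-position gaze trace with optional NA gaps.
flat_gaze <- function(n = 1000, fs = 250, x = 500, y = 400,
                      screen = default_screen()) {
  gaze_recording((seq_len(n) - 1L) / fs, rep(x, n), rep(y, n),
                 screen = screen)
}
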