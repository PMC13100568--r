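# Config-driven runners chaining the modules into reproducible
# experiment-level analyses on synthetic data. Every runner returns a
# machine-readable summary list and, when `out_dir` is given, writes it
# as JSON alongside TSV artifacts.

write_summary <- function(summary, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(summary, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_erp_tsv <- function(erps, time, path) {
  df <- data.frame(time_s = time)
  for (nm in names(erps)) df[[nm]] <- erp_trace(erps[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Emergence of ERP components and sustained slow potentials
#'
#' Simulates the two-condition viewing experiment at several trial
#' counts, and summarises the stimulus-locked grand averages: the
#' latency of the early negative trough, and the late (0.4-1.0 s)
#' window-mean difference between high- and low-exploration conditions
#' (the LPP-like sustained effect). The trough latency is stable across
#' trial counts; only the smoothness of the sustained component changes.
#'
#' @param n_trials vector of trial counts per condition
#'   (default `c(300, 1000, 5000)`).
#' @param seed master seed.
#' @param out_dir optional output directory for JSON/TSV artifacts.
#' @param noise_sd background noise sd (default 2.0 a.u.).
#' @param trough_window search window for the trough (s).
#' @param lpp_window late window for the sustained mean (s).
#' @return Summary list (one entry per trial count: `trough_latency_s`,
#'   `lpp_diff_au`, per-condition late means).
#' @export
run_figS4 <- function(n_trials = c(300, 1000, 5000), seed = 1,
                      out_dir = NULL, noise_sd = 2.0,
                      trough_window = c(0.100, 0.250),
                      lpp_window = c(0.400, 1.000)) {
  runs <- lapply(n_trials, function(nt) {
    cfg <- sim_preset("figS4", n_trials = nt, seed = seed,
                      noise_sd = noise_sd)
    sim <- simulate_experiment(cfg)
    ep <- baseline_correct(sim$epochs)
    grand <- average(ep)
    by_cond <- average(ep, by = "condition")
    trough <- component_latency(grand, trough_window, "negative")
    lpp <- vapply(by_cond, window_mean, numeric(1), window = lpp_window)
    if (!is.null(out_dir)) {
      write_erp_tsv(c(list(grand = grand), by_cond), ep$time,
                    file.path(out_dir, sprintf("figS4_erp_n%d.tsv", nt)))
    }
    list(n_trials = nt,
         trough_latency_s = as.numeric(trough),
         lpp_high_au = unname(lpp["high"]),
         lpp_low_au = unname(lpp["low"]),
         lpp_diff_au = unname(lpp["high"] - lpp["low"]))
  })
  summary <- list(experiment = "figS4", seed = seed, runs = runs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_summary(summary, out_dir, "figS4_summary")
  }
  summary
}

#' Emergence of alpha-band power from fixation-control events
#'
#' Simulates the fixation-control world, computes the Hanning-taper TFR,
#' averages power over the pre-stimulus fixation interval, removes the
#' aperiodic 1/f trend, and reports the frequency of maximal periodic
#' power along with fixation vs exploration alpha band power. No
#' oscillatory source exists in the generative model; any spectral peak
#' arises from event-timing statistics alone.
#'
#' @param n_trials trials per condition (default 1000).
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @param noise_sd background noise sd.
#' @param fixation_window pre-stimulus interval for the fixation
#'   spectrum (default `c(-1.75, -0.25)` s).
#' @param task_window post-stimulus interval for the exploration
#'   comparison (default `c(0.5, 1.75)` s).
#' @return Summary list with `peak_frequency_hz`, `alpha_fixation`,
#'   `alpha_task`, `control_erp_max_abs`.
#' @export
run_figS5 <- function(n_trials = 1000, seed = 1, out_dir = NULL,
                      noise_sd = 2.0, fixation_window = c(-1.75, -0.25),
                      task_window = c(0.5, 1.75)) {
  cfg <- sim_preset("figS5", n_trials = n_trials, seed = seed,
                    noise_sd = noise_sd)
  sim <- simulate_experiment(cfg)
  tfr <- tfr_hanning(sim$epochs, keep_trials = FALSE)
  fsel <- tfr$times >= fixation_window[1] & tfr$times < fixation_window[2]
  spec <- apply(tfr$power[1, 1, , fsel, drop = FALSE], 3, mean, na.rm = TRUE)
  ap <- remove_aperiodic(tfr$freqs, spec)
  peak <- tfr$freqs[which.max(ap$residual)]
  alpha <- band_power(tfr, band = c(8, 12))
  alpha_fix <- mean(alpha[fsel], na.rm = TRUE)
  alpha_task <- mean(alpha[tfr$times >= task_window[1] &
                             tfr$times < task_window[2]], na.rm = TRUE)
  # ERP over the fixation interval: the control events must cancel
  erp <- average(sim$epochs)
  bsel <- erp$time >= fixation_window[1] & erp$time < fixation_window[2]
  ctrl_erp <- max(abs(erp_trace(erp)[bsel]))
  summary <- list(experiment = "figS5", seed = seed, n_trials = n_trials,
                  peak_frequency_hz = peak,
                  alpha_fixation = alpha_fix, alpha_task = alpha_task,
                  control_erp_max_abs = ctrl_erp,
                  aperiodic_slope = ap$slope)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(freq_hz = tfr$freqs, power = spec, residual = ap$residual),
      file.path(out_dir, "figS5_fixation_spectrum.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_summary(summary, out_dir, "figS5_summary")
  }
  summary
}

#' Saccade-latency binning and saccade-locked re-alignment
#'
#' Sorts trials by first-saccade latency (150-300 ms window), bins them
#' into quantile bins, and contrasts the per-bin trough latency of
#' stimulus-locked versus saccade-locked averages. Stimulus-locked
#' troughs shift with the bin; saccade-locked troughs converge at the
#' kernel's pre-saccadic lag.
#'
#' @param n_trials trials per condition (default 1000).
#' @param seed master seed.
#' @param n_bins latency bins (default 4).
#' @param out_dir optional output directory.
#' @param noise_sd background noise sd.
#' @return Summary list: per-bin latencies and troughs, saccade leads,
#'   between-bin trough-latency sd for both alignments, and the sd
#'   reduction fraction.
#' @export
run_binning <- function(n_trials = 1000, seed = 1, n_bins = 4,
                        out_dir = NULL, noise_sd = 2.0) {
  cfg <- sim_preset("figS4", n_trials = n_trials, seed = seed,
                    noise_sd = noise_sd)
  sim <- simulate_experiment(cfg)
  ep <- baseline_correct(sim$epochs)
  binned <- bin_by_saccade_latency(ep, n_bins = n_bins)
  stim_erps <- average(binned, by = "bin_index", min_n = 2)
  sacc <- realign_to_saccade(binned)
  sacc_erps <- average(sacc, by = "bin_index", min_n = 2)

  mean_lat <- tapply(binned$meta$first_saccade_latency,
                     binned$meta$bin_index, mean)
  stim_trough <- vapply(stim_erps, component_latency, numeric(1),
                        search_window = c(0.020, 0.280), polarity = "negative")
  sacc_trough <- vapply(sacc_erps, component_latency, numeric(1),
                        search_window = c(-0.200, -0.050),
                        polarity = "negative")
  leads_ms <- -sacc_trough * 1000
  sd_stim <- stats::sd(stim_trough)
  sd_sacc <- stats::sd(sacc_trough)
  summary <- list(experiment = "binning", seed = seed, n_bins = n_bins,
                  bin_mean_latency_s = as.numeric(mean_lat),
                  stim_trough_s = unname(stim_trough),
                  sacc_trough_s = unname(sacc_trough),
                  saccade_lead_ms = unname(leads_ms),
                  sd_stim_locked_s = sd_stim, sd_saccade_locked_s = sd_sacc,
                  sd_reduction = 1 - sd_sacc / sd_stim)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_erp_tsv(stim_erps, binned$time,
                  file.path(out_dir, "binning_stimulus_locked.tsv"))
    write_erp_tsv(sacc_erps, sacc$time,
                  file.path(out_dir, "binning_saccade_locked.tsv"))
    write_summary(summary, out_dir, "binning_summary")
  }
  summary
}

#' Stratification of a velocity-driven late-positivity effect
#'
#' Generates a synthetic world in which the single-trial LPP amplitude
#' is driven entirely by mean epoch eye velocity, which differs between
#' two conditions. Stratifying the velocity distributions (equal per-bin
#' counts) removes the condition difference in velocity — and with it
#' most of the apparent LPP condition effect.
#'
#' @param n_per_cond trials per condition (default 300).
#' @param seed master seed.
#' @param beta LPP amplitude per unit standardized velocity (a.u.).
#' @param delta condition separation of mean velocity in sd units
#'   (default 1.0).
#' @param out_dir optional output directory.
#' @return Summary list: pre/post Cohen's d of the LPP window mean,
#'   effect-size reduction fraction, pre/post velocity means, cluster p
#'   values, kept trial counts.
#' @export
run_stratification <- function(n_per_cond = 300, seed = 1, beta = 1.0,
                               delta = 1.0, out_dir = NULL) {
  fs <- 250
  time <- seq(-0.2, 1.2, by = 1 / fs)
  n_time <- length(time)
  lpp_shape <- exp(-(time - 0.7)^2 / (2 * 0.18^2))  # smooth 0.4-1.0 s bump
  vel <- with_seed(derive_seed(seed, 9, 1), {
    list(a = stats::rnorm(n_per_cond, 200 + 40 * delta, 40),
         b = stats::rnorm(n_per_cond, 200, 40))
  })
  make_trials <- function(v, sub) {
    t(vapply(seq_along(v), function(i) {
      beta * (v[i] - 150) / 100 * lpp_shape +
        noise_1f(n_time, fs, 1, 1.0, seed = derive_seed(seed, 9, sub, i))
    }, numeric(n_time)))
  }
  A <- make_trials(vel$a, 2)
  B <- make_trials(vel$b, 3)
  wsel <- time >= 0.4 & time < 1.0
  wm_a <- rowMeans(A[, wsel])
  wm_b <- rowMeans(B[, wsel])
  d_of <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  }
  pre_d <- d_of(wm_a, wm_b)
  pre_cluster <- cluster_permutation_test(A, B, paired = FALSE,
                                          n_perm = 500,
                                          seed = derive_seed(seed, 9, 4))
  strat <- stratify(vel$a, vel$b, n_bins = 20, seed = derive_seed(seed, 9, 5))
  post_d <- d_of(wm_a[strat$keep_a], wm_b[strat$keep_b])
  post_cluster <- cluster_permutation_test(A[strat$keep_a, , drop = FALSE],
                                           B[strat$keep_b, , drop = FALSE],
                                           paired = FALSE, n_perm = 500,
                                           seed = derive_seed(seed, 9, 6))
  min_p <- function(cl) if (nrow(cl$clusters)) min(cl$clusters$p) else 1
  summary <- list(
    experiment = "stratification", seed = seed,
    n_per_cond = n_per_cond,
    velocity_diff_pre = mean(vel$a) - mean(vel$b),
    velocity_diff_post = unname(strat$post["mean_a"] - strat$post["mean_b"]),
    n_kept = c(a = length(strat$keep_a), b = length(strat$keep_b)),
    lpp_d_pre = pre_d, lpp_d_post = post_d,
    d_reduction = 1 - abs(post_d) / abs(pre_d),
    cluster_p_pre = min_p(pre_cluster),
    cluster_p_post = min_p(post_cluster),
    bins_equal = all(strat$counts$kept ==
                       pmin(strat$counts$n_a, strat$counts$n_b)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_summary(summary, out_dir, "stratification_summary")
  }
  summary
}
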