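test_that("identical paired data produce no significant clusters", {
  set.seed(1)
  A <- matrix(rnorm(15 * 40), 15, 40)
  res <- cluster_permutation_test(A, A, paired = TRUE, n_perm = 200,
                                  seed = 1)
  expect_equal(nrow(res$clusters), 0L)
  expect_warning(cluster_permutation_test(A, A + rnorm(600, 0, 1),
                                          paired = TRUE, n_perm = 10,
                                          seed = 1), "resolution")
})

test_that("a planted 2D effect is detected and covered", {
  set.seed(5)
  A <- array(rnorm(40 * 20 * 30), dim = c(40, 20, 30))
  B <- array(rnorm(40 * 20 * 30), dim = c(40, 20, 30))
  A[, 5:10, 10:20] <- A[, 5:10, 10:20] + 1.5
  res <- cluster_permutation_test(A, B, paired = TRUE, n_perm = 500,
                                  seed = 2)
  expect_lte(min(res$clusters$p), 0.05)
  expect_gte(mean(res$mask[5:10, 10:20] > 0), 0.9)
  # Cohen's d map reflects the planted effect size
  expect_equal(mean(res$d_map[5:10, 10:20]), 1.5 / sqrt(2), tolerance = 0.2)
})

test_that("permutation p-values are invariant to monotone scaling", {
  set.seed(7)
  A <- matrix(rnorm(12 * 50), 12, 50)
  B <- matrix(rnorm(12 * 50, 0.4), 12, 50)
  r1 <- cluster_permutation_test(A, B, paired = TRUE, n_perm = 300, seed = 3)
  r2 <- cluster_permutation_test(3.7 * A, 3.7 * B, paired = TRUE,
                                 n_perm = 300, seed = 3)
  expect_equal(r1$clusters$p, r2$clusters$p)
  expect_equal(r1$mask, r2$mask)
  expect_equal(r1$t_map, r2$t_map, tolerance = 1e-9)
})

test_that("unpaired cluster test detects a group offset", {
  set.seed(8)
  A <- matrix(rnorm(25 * 60), 25, 60)
  B <- matrix(rnorm(25 * 60), 25, 60)
  A[, 20:40] <- A[, 20:40] + 1.2
  res <- cluster_permutation_test(A, B, paired = FALSE, n_perm = 400,
                                  seed = 4)
  expect_lte(min(res$clusters$p), 0.05)
  big <- res$clusters[which.min(res$clusters$p), ]
  expect_gt(big$mass, 0)
})

test_that("stratification equalizes distributions and per-bin counts", {
  set.seed(11)
  a <- rnorm(2000, 0, 1)
  b <- rnorm(2000, 2, 1)
  s <- stratify(a, b, n_bins = 20, seed = 1)
  expect_true(all(s$counts$kept == pmin(s$counts$n_a, s$counts$n_b)))
  expect_equal(length(s$keep_a), length(s$keep_b))
  expect_lt(abs(mean(a[s$keep_a]) - mean(b[s$keep_b])), 0.1)
  # kept trials live where the other condition also has mass: within one
  # bin width of the other sample's range
  bw <- diff(s$edges[1:2])
  expect_gte(min(a[s$keep_a]), min(b) - bw)
  expect_lte(max(b[s$keep_b]), max(a) + bw)
  # identical samples: everything is kept
  s2 <- stratify(a, a, n_bins = 20, seed = 1)
  expect_equal(length(s2$keep_a), length(a))
  # zero overlap: empty selection, flagged
  s3 <- stratify(rnorm(50), rnorm(50) + 100, n_bins = 10, seed = 1)
  expect_true(s3$empty)
  expect_length(s3$keep_a, 0L)
})

test_that("stratification shrinks the mean difference to within one bin width", {
  # per-bin counts are equal, so the post-selection mean difference is a
  # convex combination of within-bin differences, each below the bin
  # width; when the pre-difference exceeds that, it must shrink
  set.seed(13)
  for (r in 1:20) {
    a <- rnorm(300, runif(1, -1, 1), runif(1, 0.5, 2))
    b <- rnorm(300, runif(1, -1, 1), runif(1, 0.5, 2))
    s <- stratify(a, b, n_bins = 15, seed = r)
    if (length(s$keep_a) == 0) next
    bw <- diff(s$edges[1:2])
    pre <- abs(mean(a) - mean(b))
    post <- abs(mean(a[s$keep_a]) - mean(b[s$keep_b]))
    expect_lte(post, bw + 1e-9)
    if (pre > bw) expect_lt(post, pre)
  }
})

test_that("surrogate correlation: floor at maximal correlation, detects co-modulation", {
  set.seed(17)
  x <- rnorm(400)
  out <- surrogate_corr(x, x, n_shifts = 300, seed = 1)
  expect_equal(out$r, 1)
  expect_equal(out$p, 1 / (out$n_shifts + 1))
  # slow co-modulation -> significant positive r
  t <- seq_len(400)
  s <- sin(2 * pi * t / 150)
  y1 <- s + rnorm(400, 0, 0.5)
  y2 <- s + rnorm(400, 0, 0.5)
  out2 <- surrogate_corr(y1, y2, n_shifts = 300, seed = 2)
  expect_gt(out2$r, 0.3)
  expect_lte(out2$p, 0.05)
  expect_error(surrogate_corr(rep(1, 100), rnorm(100)), "constant")
})

test_that("mixed model recovers a planted state effect", {
  set.seed(19)
  n_subj <- 40
  n_trial <- 100
  tab <- do.call(rbind, lapply(seq_len(n_subj), function(s) {
    disp <- rnorm(n_trial)
    state <- rep(c("baseline", "task"), each = n_trial / 2)
    data.frame(subject = sprintf("s%02d", s), state = state,
               gaze_dispersion = disp,
               alpha_power = rnorm(1, 0, 0.5) - 1.0 * (state == "task") +
                 rnorm(n_trial, 0, 1))
  }))
  fit <- lmm_trial_model(tab)
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "statetask"], -1.0, tolerance = 0.1)
  expect_false(fit$singular)
  expect_error(lmm_trial_model(tab[tab$subject == "s01", ]), "subjects")
})

test_that("mixed-model CI covers zero when no dispersion effect exists", {
  set.seed(23)
  cover <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    tab <- do.call(rbind, lapply(1:12, function(s) {
      state <- rep(c("baseline", "task"), each = 15)
      data.frame(subject = s, state = state,
                 gaze_dispersion = rnorm(30),
                 alpha_power = rnorm(1) + 0.5 * (state == "task") +
                   rnorm(30))
    }))
    est <- suppressMessages(lmm_trial_model(tab))$coefficients
    row <- est[est$term == "gaze_dispersion", ]
    if (abs(row$estimate) <= 1.96 * row$se) cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.90)
})

test_that("trial-level interaction reproduces the baseline-only slope pattern", {
  set.seed(29)
  tab <- do.call(rbind, lapply(1:20, function(s) {
    disp <- rnorm(120)
    state <- rep(c("baseline", "task"), each = 60)
    slope <- ifelse(state == "baseline", -0.6, 0)
    data.frame(subject = s, state = state, gaze_dispersion = disp,
               alpha_power = rnorm(1, 0, 0.3) + slope * disp +
                 rnorm(120, 0, 0.8))
  }))
  est <- lmm_trial_model(tab)$coefficients
  inter <- est[est$term == "statetask:gaze_dispersion", ]
  expect_lt(inter$p, 0.05)
  expect_gt(inter$estimate, 0)   # slope relaxes toward 0 in the task state
  base_slope <- est[est$term == "gaze_dispersion", ]
  expect_lt(base_slope$estimate, 0)
})

test_that("2x2 repeated-measures ANOVA matches its contrast decomposition", {
  # identical values everywhere -> all F = 0
  d0 <- expand.grid(subject = 1:8, state = c("baseline", "task"),
                    measure = c("alpha", "dispersion"))
  d0$value <- 5
  a0 <- rm_anova_2x2(d0)
  expect_true(all(a0$F == 0))

  # planted pure interaction: opposite state effects for the two measures
  set.seed(31)
  d1 <- expand.grid(subject = 1:16, state = c("baseline", "task"),
                    measure = c("alpha", "dispersion"))
  eff <- with(d1, ifelse(measure == "alpha", 1, -1) *
                ifelse(state == "baseline", 1, -1))
  d1$value <- eff + rnorm(nrow(d1), 0, 0.4)
  a1 <- rm_anova_2x2(d1)
  Fi <- a1$F[a1$effect == "State:Measure"]
  expect_gt(Fi, 10 * max(a1$F[a1$effect != "State:Measure"]))
  expect_lt(a1$p[a1$effect == "State:Measure"], 0.001)

  # dual-route check against R's aov() on random data
  set.seed(33)
  d2 <- expand.grid(subject = factor(1:10), state = c("s1", "s2"),
                    measure = c("m1", "m2"))
  d2$value <- rnorm(nrow(d2))
  mine <- rm_anova_2x2(d2)
  ref <- summary(stats::aov(value ~ state * measure +
                              Error(subject / (state * measure)),
                            data = d2))
  refF <- c(State = ref[["Error: subject:state"]][[1]]["state", "F value"],
            Measure = ref[["Error: subject:measure"]][[1]]["measure", "F value"],
            `State:Measure` = ref[["Error: subject:state:measure"]][[1]][
              "state:measure", "F value"])
  expect_equal(mine$F, unname(refF[mine$effect]), tolerance = 1e-8)

  expect_error(rm_anova_2x2(d2[-1, ]), "missing")
})

test_that("channel adjacency links posterior neighbours but not distant sites", {
  adj <- channel_adjacency(c("O1", "O2", "Fz", "POz"))
  expect_true(2L %in% adj[[1]] || 4L %in% adj[[1]])  # O1 near O2/POz
  expect_false(3L %in% adj[[1]])                     # O1 far from Fz
})
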