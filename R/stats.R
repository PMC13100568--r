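# Statistical procedures: cluster-based permutation tests over
# channel/time/frequency lattices (and gaze grids), distribution
# stratification, circular-shift surrogate correlations, trial-level
# mixed models and the 2x2 repeated-measures ANOVA contract.

# Build an adjacency list for a lattice described by `dims`:
# 1D -> chain neighbours, 2D -> 4-connectivity.
grid_adjacency <- function(dims) {
  if (length(dims) == 1L) {
    P <- dims
    return(lapply(seq_len(P), function(i) {
      c(if (i > 1) i - 1L, if (i < P) i + 1L)
    }))
  }
  if (length(dims) == 2L) {
    nr <- dims[1]; nc <- dims[2]
    idx <- function(r, c) (c - 1L) * nr + r
    lapply(seq_len(nr * nc), function(p) {
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      c(if (r > 1) idx(r - 1L, c), if (r < nr) idx(r + 1L, c),
        if (c > 1) idx(r, c - 1L), if (c < nc) idx(r, c + 1L))
    })
  } else {
    stop("grid adjacency supports 1D and 2D lattices; supply `neighborhood`")
  }
}

#' Channel adjacency from 10-20 template positions
#'
#' Neighbours are electrode pairs closer than `max_dist_mm` on a
#' spherical-head template (radius 95 mm) of standard 10-20 positions.
#'
#' @param labels channel labels.
#' @param max_dist_mm distance threshold in millimetres (default 100).
#' @return Adjacency list (integer neighbour indices per channel).
#' @export
channel_adjacency <- function(labels, max_dist_mm = 100) {
  pos <- ten_twenty_positions()
  m <- match(toupper(labels), toupper(rownames(pos)))
  if (anyNA(m)) stop("no template position for: ",
                     paste(labels[is.na(m)], collapse = ", "))
  xyz <- pos[m, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  lapply(seq_along(labels), function(i) which(d[i, ] <= max_dist_mm & seq_along(labels) != i))
}

# Approximate spherical 10-20 electrode coordinates (mm), head radius 95.
ten_twenty_positions <- function() {
  ang <- rbind( # theta (from vertex, deg), phi (azimuth from nasion, deg, counterclockwise)
    Fp1 = c(92, 72), Fp2 = c(92, -72) + c(0, 360) * 0, Fpz = c(92, 90),
    F7 = c(92, 36), F3 = c(60, 51), Fz = c(46, 90), F4 = c(60, 129),
    F8 = c(92, 144), T7 = c(92, 0), C3 = c(46, 0), Cz = c(0, 0),
    C4 = c(46, 180), T8 = c(92, 180), P7 = c(92, -36), P3 = c(60, -51),
    Pz = c(46, -90), P4 = c(60, -129), P8 = c(92, -144), O1 = c(92, -72),
    Oz = c(92, -90), O2 = c(92, -108), POz = c(69, -90), AFz = c(69, 90),
    FCz = c(23, 90), CPz = c(23, -90))
  th <- ang[, 1] * pi / 180
  ph <- ang[, 2] * pi / 180
  r <- 95
  cbind(x = r * sin(th) * cos(ph), y = r * sin(th) * sin(ph),
        z = r * cos(th))
}

# Connected components of `active` points under adjacency `adj`.
# Returns an integer label vector (0 = inactive).
label_components <- function(active, adj) {
  labels <- integer(length(active))
  comp <- 0L
  for (s in which(active)) {
    if (labels[s]) next
    comp <- comp + 1L
    stack <- s
    labels[s] <- comp
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (q in adj[[p]]) {
        if (active[q] && !labels[q]) {
          labels[q] <- comp
          stack <- c(stack, q)
        }
      }
    }
  }
  labels
}

# Max absolute signed-cluster mass of a t-map (used for the permutation
# null). 1D lattices use an rle fast path.
max_cluster_mass <- function(tvec, tcrit, adj, dims) {
  if (length(dims) == 1L) {
    out <- 0
    for (sgn in c(1, -1)) {
      act <- sgn * tvec > tcrit
      if (!any(act)) next
      r <- rle(act)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        out <- max(out, abs(sum(tvec[starts[j]:ends[j]])))
      }
    }
    return(out)
  }
  out <- 0
  for (sgn in c(1, -1)) {
    act <- sgn * tvec > tcrit
    if (!any(act)) next
    lab <- label_components(act, adj)
    if (max(lab)) {
      out <- max(out, max(abs(tapply(tvec[act], lab[act], sum))))
    }
  }
  out
}

#' Cluster-based permutation test
#'
#' Pointwise t statistics (paired/one-sample against zero difference, or
#' two-sample pooled-variance) are thresholded at the two-tailed
#' cluster-forming quantile; contiguous supra-threshold points (grid
#' 4-connectivity by default, or a supplied adjacency list) are summed
#' into signed cluster masses; the null distribution of the maximal
#' absolute mass is built from sign flips (paired) or label shuffles
#' (unpaired). Controls the family-wise error over the whole lattice.
#'
#' @param data_a,data_b numeric arrays `units x <lattice dims>`; for
#'   paired tests the unit counts must match (set `data_b = NULL` for a
#'   one-sample test of `data_a` against 0).
#' @param paired logical.
#' @param neighborhood `NULL` (grid adjacency from the lattice dims) or
#'   an adjacency list over flattened lattice points.
#' @param n_perm number of permutations (default 500).
#' @param alpha cluster significance level (default 0.05).
#' @param cluster_alpha two-tailed p threshold forming clusters
#'   (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @return An object of class `oculo_clusters`: `t_map` and `d_map`
#'   (Cohen's d) in lattice shape, `clusters` (data.frame: id, sign,
#'   mass, n_points, p), `mask` (lattice-shaped cluster ids for clusters
#'   with p <= alpha), `null_max`, `n_permutations`, `alpha`.
#' @export
cluster_permutation_test <- function(data_a, data_b = NULL, paired = FALSE,
                                     neighborhood = NULL, n_perm = 500,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     seed = NULL) {
  if (n_perm < 1 / alpha) {
    warning("n_perm < 1/alpha: p-value resolution cannot reach alpha")
  }
  da <- as.array(data_a)
  dims <- dim(da)[-1]
  if (is.null(dims)) dims <- length(da) / dim(da)[1]
  A <- matrix(da, nrow = dim(da)[1])
  P <- ncol(A)
  adj <- neighborhood %||% (if (length(dims) == 1L) NULL else grid_adjacency(dims))

  if (paired || is.null(data_b)) {
    D <- if (is.null(data_b)) A else A - matrix(as.array(data_b), nrow = nrow(A))
    n <- nrow(D)
    df <- n - 1
    ss <- colSums(D^2)
    m <- colMeans(D)
    tstat <- t_from_moments(m, ss, n)
    dmap <- m / sqrt(pmax((ss - n * m^2) / (n - 1), 0))
    tcrit <- stats::qt(1 - cluster_alpha / 2, df)
    S <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                nrow = n_perm))
    M <- (S %*% D) / n
    null_max <- vapply(seq_len(n_perm), function(r) {
      tv <- t_from_moments(M[r, ], ss, n)  # sum of squares invariant to sign flips
      max_cluster_mass(tv, tcrit, adj, dims)
    }, numeric(1))
  } else {
    B <- matrix(as.array(data_b), nrow = dim(as.array(data_b))[1])
    na <- nrow(A); nb <- nrow(B)
    X <- rbind(A, B)
    df <- na + nb - 2
    tcrit <- stats::qt(1 - cluster_alpha / 2, df)
    tstat <- two_sample_t(X, seq_len(na), na, nb)
    sp <- pooled_sd(X, seq_len(na), na, nb)
    dmap <- (colMeans(A) - colMeans(B)) / sp
    null_max <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
      ia <- sample.int(na + nb, na)
      tv <- two_sample_t(X, ia, na, nb)
      max_cluster_mass(tv, tcrit, adj, dims)
    }, numeric(1)))
  }

  clusters <- find_clusters(tstat, tcrit, adj, dims)
  clusters$p <- vapply(clusters$mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (n_perm + 1)
  }, numeric(1))
  mask <- integer(P)
  for (i in seq_len(nrow(clusters))) {
    if (clusters$p[i] <= alpha) mask[clusters$points[[i]]] <- i
  }
  shape <- function(v) if (length(dims) > 1L) array(v, dims) else v
  structure(list(t_map = shape(tstat), d_map = shape(dmap),
                 clusters = clusters[, c("id", "sign", "mass", "n_points", "p")],
                 cluster_points = clusters$points,
                 mask = shape(mask), null_max = null_max,
                 n_permutations = n_perm, alpha = alpha,
                 cluster_alpha = cluster_alpha),
            class = "oculo_clusters")
}

t_from_moments <- function(m, ss, n) {
  v <- pmax((ss - n * m^2) / (n - 1), 0)
  t <- m / sqrt(v / n)
  t[v == 0] <- 0
  t
}

two_sample_t <- function(X, ia, na, nb) {
  A <- X[ia, , drop = FALSE]
  B <- X[-ia, , drop = FALSE]
  ma <- colMeans(A); mb <- colMeans(B)
  sp <- sqrt(((na - 1) * apply(A, 2, stats::var) +
                (nb - 1) * apply(B, 2, stats::var)) / (na + nb - 2))
  t <- (ma - mb) / (sp * sqrt(1 / na + 1 / nb))
  t[sp == 0] <- 0
  t
}

pooled_sd <- function(X, ia, na, nb) {
  A <- X[ia, , drop = FALSE]
  B <- X[-ia, , drop = FALSE]
  sqrt(((na - 1) * apply(A, 2, stats::var) +
          (nb - 1) * apply(B, 2, stats::var)) / (na + nb - 2))
}

find_clusters <- function(tvec, tcrit, adj, dims) {
  rows <- list()
  id <- 0L
  for (sgn in c(1, -1)) {
    act <- sgn * tvec > tcrit
    if (!any(act)) next
    lab <- if (length(dims) == 1L) {
      l <- integer(length(act))
      r <- rle(act)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      k <- 0L
      for (j in which(r$values)) {
        k <- k + 1L
        l[starts[j]:ends[j]] <- k
      }
      l
    } else {
      label_components(act, adj)
    }
    for (k in seq_len(max(lab))) {
      pts <- which(lab == k)
      id <- id + 1L
      rows[[id]] <- data.frame(id = id, sign = sgn,
                               mass = sum(tvec[pts]),
                               n_points = length(pts))
      rows[[id]]$points <- list(pts)
    }
  }
  if (!length(rows)) {
    out <- data.frame(id = integer(0), sign = numeric(0), mass = numeric(0),
                      n_points = integer(0))
    out$points <- list()
    return(out)
  }
  do.call(rbind, rows)
}

#' @export
print.oculo_clusters <- function(x, ...) {
  cat(sprintf("<oculo_clusters> %d cluster(s), %d permutations, alpha %.3g\n",
              nrow(x$clusters), x$n_permutations, x$alpha))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Distribution stratification
#'
#' Matches the distributions of a nuisance variable across two trial
#' sets: common histogram bins span the pooled range; within each bin,
#' `min(count_a, count_b)` trials are kept from each side (uniform
#' subsample, seeded). Values from non-overlapping parts of the
#' distributions are thereby removed, nullifying the condition
#' difference in the stratified variable.
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @param n_bins number of common bins (default 20).
#' @param seed integer seed for the subsampling.
#' @return An object of class `oculo_stratified`: `keep_a`, `keep_b`
#'   (kept indices), `edges`, `counts` (per-bin kept/original counts),
#'   `pre` and `post` mean summaries.
#' @export
stratify <- function(values_a, values_b, n_bins = 20, seed = NULL) {
  if (!length(values_a) || !length(values_b)) stop("both samples must be non-empty")
  rng <- range(c(values_a, values_b), finite = TRUE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin_of <- function(v) pmin(pmax(findInterval(v, edges,
                                               rightmost.closed = TRUE), 1L),
                             n_bins)
  ba <- bin_of(values_a)
  bb <- bin_of(values_b)
  counts <- data.frame(bin = seq_len(n_bins), n_a = 0L, n_b = 0L, kept = 0L)
  sel <- with_seed(seed, {
    ka <- integer(0)
    kb <- integer(0)
    for (b in seq_len(n_bins)) {
      ia <- which(ba == b)
      ib <- which(bb == b)
      k <- min(length(ia), length(ib))
      counts$n_a[b] <- length(ia)
      counts$n_b[b] <- length(ib)
      counts$kept[b] <- k
      if (k > 0) {
        ka <- c(ka, if (length(ia) == k) ia else sample(ia, k))
        kb <- c(kb, if (length(ib) == k) ib else sample(ib, k))
      }
    }
    list(ka = ka, kb = kb, counts = counts)
  })
  counts <- sel$counts
  keep_a <- sort(sel$ka)
  keep_b <- sort(sel$kb)
  flagged <- length(keep_a) == 0
  structure(list(keep_a = keep_a, keep_b = keep_b, edges = edges,
                 counts = counts, empty = flagged,
                 pre = c(mean_a = mean(values_a), mean_b = mean(values_b)),
                 post = c(mean_a = if (length(keep_a)) mean(values_a[keep_a]) else NA_real_,
                          mean_b = if (length(keep_b)) mean(values_b[keep_b]) else NA_real_)),
            class = "oculo_stratified")
}

#' Circular-shift surrogate correlation
#'
#' The observed Pearson correlation is contrasted against a null built
#' by circularly shifting one series at offsets sampled without
#' replacement (shifts closer than 5% of the series length to zero are
#' excluded, so surrogates stay decorrelated from the original
#' alignment).
#'
#' @param x,y numeric series of equal length (>= 10).
#' @param n_shifts number of surrogate shifts (default 500; capped at
#'   the number of admissible offsets).
#' @param seed integer seed.
#' @return list with `r` (observed), `p` (two-sided empirical, +1
#'   corrected), `null` (surrogate r values), `n_shifts`.
#' @export
surrogate_corr <- function(x, y, n_shifts = 500, seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 10)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant series")
  }
  r_obs <- stats::cor(x, y)
  min_shift <- max(1L, ceiling(0.05 * n))
  offsets <- seq.int(min_shift, n - min_shift)
  m <- min(n_shifts, length(offsets))
  sel <- with_seed(seed, if (m < length(offsets)) sample(offsets, m) else offsets)
  null <- vapply(sel, function(s) {
    stats::cor(x, y[c((s + 1):n, 1:s)])
  }, numeric(1))
  list(r = r_obs, p = (1 + sum(abs(null) >= abs(r_obs))) / (m + 1),
       null = null, n_shifts = m)
}

#' Trial-level mixed model of alpha power
#'
#' Contract for the single-trial analysis: fits
#' `alpha_power ~ state * gaze_dispersion + (1 | subject)` with an
#' established mixed-model solver (lme4). p-values use the normal (Wald
#' z) approximation of the t statistics, since the solver reports no
#' denominator degrees of freedom.
#'
#' @param table data.frame with columns `alpha_power`,
#'   `gaze_dispersion`, `state` (2-level factor), `subject`.
#' @return list with `coefficients` (estimate, se, t, p per fixed
#'   effect), `singular` (logical singular-fit signal), `model` (the
#'   lme4 fit).
#' @export
lmm_trial_model <- function(table) {
  need <- c("alpha_power", "gaze_dispersion", "state", "subject")
  if (!all(need %in% names(table))) {
    stop("table must contain: ", paste(need, collapse = ", "))
  }
  if (length(unique(table$subject)) < 2) stop("need >= 2 subjects")
  if (length(unique(table$state)) < 2) stop("need >= 2 states")
  fit <- lme4::lmer(alpha_power ~ state * gaze_dispersion + (1 | subject),
                    data = table, REML = TRUE)
  co <- summary(fit)$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], t = co[, "t value"],
                    p = 2 * stats::pnorm(-abs(co[, "t value"])),
                    row.names = NULL)
  list(coefficients = out, singular = lme4::isSingular(fit), model = fit)
}

#' 2x2 repeated-measures ANOVA (State x Measure)
#'
#' Classical within-subject decomposition for a complete 2x2 design:
#' each 1-df effect is a per-subject contrast `c_i`, with
#' `F = n * mean(c)^2 / var(c)` on (1, n-1) degrees of freedom.
#'
#' @param subject_means data.frame with columns `subject`, `state`,
#'   `measure`, `value`; every subject must have all four cells.
#' @return data.frame with `effect`, `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(subject_means) {
  d <- subject_means
  states <- sort(unique(as.character(d$state)))
  measures <- sort(unique(as.character(d$measure)))
  subjects <- unique(d$subject)
  if (length(states) != 2 || length(measures) != 2) {
    stop("need exactly 2 states and 2 measures")
  }
  cell <- function(su, st, me) {
    v <- d$value[d$subject == su & d$state == st & d$measure == me]
    if (length(v) != 1) stop("missing or duplicated cell: ",
                             su, "/", st, "/", me)
    v
  }
  m <- t(vapply(subjects, function(su) {
    c(cell(su, states[1], measures[1]), cell(su, states[1], measures[2]),
      cell(su, states[2], measures[1]), cell(su, states[2], measures[2]))
  }, numeric(4)))
  n <- nrow(m)
  contrasts <- list(
    State = (m[, 1] + m[, 2] - m[, 3] - m[, 4]) / 2,
    Measure = (m[, 1] - m[, 2] + m[, 3] - m[, 4]) / 2,
    `State:Measure` = (m[, 1] - m[, 2] - m[, 3] + m[, 4]) / 2)
  out <- lapply(names(contrasts), function(nm) {
    cc <- contrasts[[nm]]
    v <- stats::var(cc)
    Fv <- if (v == 0) {
      if (mean(cc) == 0) 0 else Inf
    } else {
      n * mean(cc)^2 / v
    }
    data.frame(effect = nm, F = Fv, df1 = 1, df2 = n - 1,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
  })
  do.call(rbind, out)
}
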