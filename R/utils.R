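# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' One master seed drives every source of randomness in the package;
#' per-trial / per-stream sub-seeds are derived with a small documented
#' counter scheme (a 31-bit linear congruential mix over the index path),
#' so that individual trials can be re-generated in isolation.
#'
#' @param master integer master seed.
#' @param ... integer indices (condition index, trial index, stream id, ...).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) {
    # 69069 * s stays below 2^53 for s < 2^31, so double arithmetic is exact
    s <- (s * 69069 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(class = c("oculoscope_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a finite numeric scalar")
  }
}

# --- truncated normal -------------------------------------------------------

rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

ptruncnorm <- function(q, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  p <- (stats::pnorm(q, mean, sd) - plo) / (phi - plo)
  pmin(pmax(p, 0), 1)
}

truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Half-open interval membership [lo, hi)
in_window <- function(x, window) x >= window[1] & x < window[2]
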