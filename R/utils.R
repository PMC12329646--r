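#' @keywords internal
"_PACKAGE"

# Internal numeric helpers shared across modules.

#' Draw from a normal distribution truncated at +/- 3 SD
#'
#' All sampled scalars in the generator use this: it keeps the stated
#' mean/SD approximately while excluding non-physical tail draws.
#'
#' @param n number of draws
#' @param mean,sd distribution parameters; `sd = 0` returns `mean` exactly
#' @param n_sd truncation half-width in SD units (default 3)
#' @return numeric vector of length `n`
#' @keywords internal
rtruncnorm3 <- function(n, mean, sd, n_sd = 3) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0) {
    stop("invalid-configuration: non-finite or negative distribution parameters")
  }
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  # rejection sampling; acceptance probability ~0.997 so this terminates fast
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- abs(x - mean) <= n_sd * sd
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Derive a child seed from a parent seed and an index
#'
#' Splitmix-style integer hash folded into [0, 2^31): hierarchical seeding
#' lets any participant/trial be regenerated without replaying the whole
#' stream.
#' @keywords internal
child_seed <- function(seed, index) {
  # work in double precision; values stay below 2^53 so arithmetic is exact
  x <- (as.numeric(seed) * 2654435761 + as.numeric(index) * 40503 + 12345) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

#' Smooth C1 step from 0 at x=0 to 1 at x=1
#' @keywords internal
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Smooth low-amplitude noise on [0,1]
#'
#' Sum of a few random-phase Fourier modes; endpoints damped by a sine
#' envelope so waveform boundary conditions survive noise injection.
#' @param t abscissa in [0,1]
#' @param amplitude typical peak amplitude of the noise
#' @param n_modes number of Fourier modes
#' @keywords internal
smooth_noise <- function(t, amplitude, n_modes = 4) {
  if (amplitude == 0) return(numeric(length(t)))
  z <- numeric(length(t))
  for (k in seq_len(n_modes)) {
    a <- stats::rnorm(1) / k
    ph <- stats::runif(1, 0, 2 * pi)
    z <- z + a * sin(pi * k * t + ph)
  }
  amplitude * sin(pi * t) * z / sqrt(sum((1 / seq_len(n_modes))^2) / 2)
}

#' Stop with a classed condition
#' @keywords internal
stop_gaitsens <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "gaitsens_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}
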