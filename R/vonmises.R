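#' Wrap angles to [-pi, pi)
#'
#' @param a numeric vector of angles in radians.
#' @return angles wrapped into `[-pi, pi)`.
#' @export
wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

#' von Mises density
#'
#' Circular density `exp(kappa * cos(theta - mu)) / (2 pi I0(kappa))`,
#' evaluated with exponentially scaled Bessel functions so large
#' concentrations do not overflow.
#'
#' @param theta angles (radians).
#' @param mu mean direction.
#' @param kappa concentration parameter, `>= 0`; 0 gives the uniform
#'   circular density `1/(2 pi)`.
#' @return density values.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' von Mises random deviates
#'
#' Best–Fisher rejection sampler, vectorized over per-draw means and
#' concentrations (as needed by the biased-persistent walk, where the
#' combined concentration differs at every step).
#'
#' @param n number of draws.
#' @param mu mean direction(s), recycled to length `n`.
#' @param kappa concentration(s) `>= 0`, recycled to length `n`.
#' @return `n` angles in `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  stopifnot(all(kappa >= 0))
  out <- numeric(n)
  tiny <- kappa < 1e-10
  if (any(tiny)) out[tiny] <- stats::runif(sum(tiny), -pi, pi)
  idx <- which(!tiny)
  if (length(idx)) {
    k <- kappa[idx]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    got <- numeric(length(idx))
    pending <- seq_along(idx)
    while (length(pending)) {
      m <- length(pending)
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r[pending] * z) / (r[pending] + z)
      cc <- k[pending] * (r[pending] - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      if (any(ok)) {
        th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
        got[pending[ok]] <- th
        pending <- pending[!ok]
      }
    }
    out[idx] <- got + mu[idx]
  }
  wrap_angle(out)
}
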