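# von Mises sampling (Best & Fisher 1979 rejection scheme), vectorized.
# No installed package provides a circular RNG, so this is implemented
# directly and property-tested against its theoretical moments.

#' Draw from a von Mises distribution
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0); `kappa = 0` gives the uniform circle.
#' @return Angles in degrees, wrapped to `[-180, 180)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stopf("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrap_deg(stats::runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
    out[need[ok]] <- th[ok]
    need <- need[!ok]
  }
  wrap_deg(mu + out * 180 / pi)
}
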