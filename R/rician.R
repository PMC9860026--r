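# Numerics for the Rician magnitude distribution.
#
# All likelihood code works with exponentially-scaled modified Bessel
# functions so that log-densities stay finite up to SNR ~ 1e4. For large
# arguments the scaled Bessel terms are replaced by their asymptotic
# series, which is both faster and avoids the (slow) special-function
# evaluation on the bulk of high-SNR voxels.

# I1(x)/I0(x), vectorised, x >= 0. Asymptotic branch above x = 20 is
# accurate to ~2e-8; below, the scaled besselI is used directly.
bessel_i1i0_ratio <- function(x) {
  out <- numeric(length(x))
  hi <- x > 20
  if (any(hi)) {
    xi <- x[hi]
    out[hi] <- 1 - 1 / (2 * xi) - 1 / (8 * xi^2) - 1 / (8 * xi^3) -
      25 / (128 * xi^4) - 13 / (32 * xi^5)
  }
  if (any(!hi)) {
    xl <- x[!hi]
    out[!hi] <- besselI(xl, 1, expon.scaled = TRUE) /
      besselI(xl, 0, expon.scaled = TRUE)
  }
  out
}

# log(I0(x) * exp(-x)), vectorised, x >= 0.
log_bessel_i0_scaled <- function(x) {
  out <- numeric(length(x))
  hi <- x > 20
  if (any(hi)) {
    xi <- x[hi]
    out[hi] <- -0.5 * log(2 * pi * xi) +
      log1p(1 / (8 * xi) + 9 / (128 * xi^2) + 75 / (1024 * xi^3) +
            3675 / (32768 * xi^4))
  }
  if (any(!hi))
    out[!hi] <- log(besselI(x[!hi], 0, expon.scaled = TRUE))
  out
}

#' Rician log-likelihood of magnitude observations
#'
#' Log-density of magnitudes `m` under the Rician distribution with
#' noiseless signal level `nu` and complex-channel noise `sigma`:
#' `log(m/sigma^2) - (m - nu)^2 / (2 sigma^2) + log(I0(m nu / sigma^2) *
#' exp(-m nu / sigma^2))`, evaluated stably via scaled Bessel functions.
#'
#' @param m Observed magnitudes (>= 0).
#' @param nu Noiseless signal levels (recycled against `m`).
#' @param sigma Noise standard deviation (> 0).
#' @return Vector of log-density values.
#' @export
rician_loglik <- function(m, nu, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  x <- m * nu / sigma^2
  log(m) - 2 * log(sigma) - (m - nu)^2 / (2 * sigma^2) +
    log_bessel_i0_scaled(x)
}

#' Per-observation Fisher information about the Rician signal level
#'
#' Information about `nu` carried by one magnitude observation
#' `m ~ Rice(nu, sigma)`, computed by adaptive quadrature of the squared
#' score over the magnitude axis. In the Gaussian (high-SNR) limit the
#' value converges to `1/sigma^2`; at `nu = 0` there is no information.
#'
#' @param nu Noiseless signal level (>= 0); vectorised.
#' @param sigma Noise standard deviation (> 0).
#' @param rel_tol Quadrature relative tolerance.
#' @return Fisher information values (units 1/a.u.^2).
#' @export
rician_nu_information <- function(nu, sigma, rel_tol = 1e-8) {
  if (sigma <= 0) stop("'sigma' must be positive")
  vapply(nu, function(v) {
    if (v <= 0) return(0)
    integrand <- function(m) {
      x <- m * v / sigma^2
      score <- (-v + m * bessel_i1i0_ratio(x)) / sigma^2
      logp <- log(m) - 2 * log(sigma) - (m - v)^2 / (2 * sigma^2) +
        log_bessel_i0_scaled(x)
      out <- exp(2 * log(abs(score)) + logp)
      out[!is.finite(out)] <- 0
      out
    }
    res <- tryCatch(
      stats::integrate(integrand, max(0, v - 12 * sigma), v + 12 * sigma,
                       rel.tol = rel_tol, subdivisions = 400L),
      error = function(e) stop("Rician information quadrature failed at nu/sigma = ",
                               format(v / sigma), ": ", conditionMessage(e)))
    res$value
  }, numeric(1))
}
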