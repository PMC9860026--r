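# Spoiled multi-echo GRE signal model and Rician magnitude formation.

#' Tissue parameters for simulation and prediction
#'
#' @param m0 Spin density (a.u., >= 0).
#' @param t1 Longitudinal relaxation time (ms, > 0).
#' @param t2_star Effective transverse relaxation time (ms, > 0).
#' @param phi0 Initial phase (rad).
#' @param delta_f Off-resonance frequency (kHz).
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(m0 = 1, t1, t2_star, phi0 = 0, delta_f = 0) {
  if (m0 < 0) stop("'m0' must be non-negative")
  if (t1 <= 0 || t2_star <= 0) stop("'t1' and 't2_star' must be positive")
  structure(list(m0 = m0, t1 = t1, t2_star = t2_star,
                 phi0 = phi0, delta_f = delta_f),
            class = "tissue_params")
}

#' Acquisition parameters
#'
#' @param alpha Flip angle in degrees (0 < alpha <= 90).
#' @param tr Repetition time (ms, > 0).
#' @param sigma Standard deviation of the complex Gaussian noise per channel
#'   (a.u., >= 0).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(alpha, tr, sigma = 0) {
  if (alpha <= 0 || alpha > 90) stop("'alpha' must be in (0, 90] degrees")
  if (tr <= 0) stop("'tr' must be positive")
  if (sigma < 0) stop("'sigma' must be non-negative")
  structure(list(alpha = alpha, tr = tr, sigma = sigma),
            class = "acquisition_params")
}

#' Spoiled-GRE steady-state amplitude factor
#'
#' `sin(a) (1 - E1) / (1 - cos(a) E1)` with `E1 = exp(-tr/t1)`. Lies in
#' `[0, 1]` and is maximised at the Ernst angle `acos(E1)`.
#'
#' @param alpha Flip angle (degrees).
#' @param tr Repetition time (ms).
#' @param t1 Longitudinal relaxation time (ms).
#' @return Dimensionless amplitude factor.
#' @examples
#' steady_state_factor(75, 1200, 878)  # ~0.7705
#' @export
steady_state_factor <- function(alpha, tr, t1) {
  if (any(t1 <= 0) || any(tr <= 0)) stop("'tr' and 't1' must be positive")
  a <- alpha * pi / 180
  e1 <- exp(-tr / t1)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Noiseless complex multi-echo GRE signal
#'
#' Evaluates the spoiled-GRE signal at each echo time: modulus
#' `m0 * steady_state_factor * exp(-TE/t2_star)` and phase
#' `phi0 + 2 pi delta_f TE` (with `delta_f` in kHz and TE in ms). The
#' modulus is independent of phase and off-resonance, which is what
#' justifies magnitude-only fitting.
#'
#' @param tissue A [tissue_params()].
#' @param acq An [acquisition_params()].
#' @param train An [echo_train()].
#' @return Complex vector of length `train$n_e`.
#' @export
noiseless_signal <- function(tissue, acq, train) {
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(acq, "acquisition_params"),
            inherits(train, "echo_train"))
  amp <- tissue$m0 * steady_state_factor(acq$alpha, acq$tr, tissue$t1)
  te <- train$te
  amp * exp(-te / tissue$t2_star) *
    exp(1i * (tissue$phi0 + 2 * pi * tissue$delta_f * te))
}

#' Parity-dependent amplitude modulation factors
#'
#' Multiplicative amplitude factors applied to odd- and even-parity echoes
#' of a bipolar train (e.g. from the asymmetric frequency response of the
#' receiver chain). Only the ratio `g_odd / g_even` is identifiable from
#' magnitude data -- a common scale is absorbed into the fitted amplitude --
#' so estimation normalises the pair to geometric mean 1.
#'
#' @param g_odd Factor on odd-parity echoes (> 0).
#' @param g_even Factor on even-parity echoes (> 0).
#' @param normalize If `TRUE`, rescale so that `g_odd * g_even = 1`.
#' @return An object of class `parity_modulation`.
#' @export
parity_modulation <- function(g_odd = 1, g_even = 1, normalize = FALSE) {
  if (g_odd <= 0 || g_even <= 0) stop("modulation factors must be positive")
  if (normalize) {
    s <- sqrt(g_odd * g_even)
    g_odd <- g_odd / s
    g_even <- g_even / s
  }
  structure(list(g_odd = g_odd, g_even = g_even), class = "parity_modulation")
}

#' Apply parity-dependent amplitude modulation to a signal series
#'
#' Scales odd-parity entries by `g_odd` and even-parity entries by
#' `g_even`. On a constant-parity (monopolar) train this is a uniform
#' scaling, which a magnitude fit absorbs into the amplitude, leaving T2*
#' unchanged.
#'
#' @param series Complex or numeric signal series.
#' @param parity Per-echo parity labels (`"odd"`/`"even"`), same length.
#' @param mod A [parity_modulation()].
#' @return The modulated series.
#' @export
apply_parity_modulation <- function(series, parity, mod) {
  stopifnot(inherits(mod, "parity_modulation"))
  if (length(series) != length(parity)) stop("'series' and 'parity' lengths differ")
  g <- ifelse(parity == "odd", mod$g_odd, mod$g_even)
  series * g
}

#' Rician magnitude of a complex signal under Gaussian noise
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `sigma`
#' to the real and imaginary parts and returns the modulus. With
#' `sigma = 0` this is the noiseless modulus. Supplying `seed` makes the
#' draw reproducible without disturbing the caller's RNG state.
#'
#' @param series Complex signal series (numeric input is treated as real).
#' @param sigma Per-channel noise standard deviation (a.u., >= 0).
#' @param seed Optional integer seed.
#' @return Numeric magnitude series.
#' @export
to_rician_magnitude <- function(series, sigma, seed = NULL) {
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (sigma == 0) return(Mod(series))
  if (!is.null(seed))
    return(with_seed(seed, to_rician_magnitude(series, sigma)))
  n <- length(series)
  sqrt((Re(series) + stats::rnorm(n, 0, sigma))^2 +
       (Im(series) + stats::rnorm(n, 0, sigma))^2)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
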