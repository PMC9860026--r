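# Noise estimation and Rician-likelihood T2* fitting.
#
# The model is the two-parameter mono-exponential nu_n = A exp(-TE_n/T2*)
# with the complex-channel noise sigma treated as known (estimated once
# from the noise-only background). The Rician maximum-likelihood estimate
# is found by Gauss-Newton iteration on the score equations: at the
# current signal estimate the observed magnitudes are replaced by the
# pseudo-data m * I1(m nu / s^2) / I0(m nu / s^2), after which one damped
# Gauss-Newton least-squares step is taken; at a fixed point the exact
# Rician score is zero. With sigma = 0 (or noise_model = "gaussian") the
# pseudo-data are the magnitudes themselves and the scheme reduces to
# ordinary nonlinear least squares.

#' Estimate the complex-channel noise level from background magnitudes
#'
#' Converts noise-only (Rayleigh-distributed) background magnitudes to the
#' underlying complex Gaussian sigma. The default uses the second moment,
#' `sigma = sqrt(mean(M^2) / 2)`; the mean-based alternative uses
#' `sigma = mean(M) / sqrt(pi/2)`. All echoes of every masked voxel are
#' pooled.
#'
#' @param stack A [simulate_series()] result or a 3-D magnitude array
#'   (rows x columns x echoes).
#' @param masks A logical matrix, or list of logical matrices (e.g.
#'   [corner_masks()]), selecting noise-only voxels.
#' @param method `"second_moment"` (default) or `"mean"`.
#' @return An object of class `noise_estimate`: `sigma`, `n_voxels`
#'   (spatial voxels pooled), `method`.
#' @export
estimate_noise_background <- function(stack, masks,
                                      method = c("second_moment", "mean")) {
  method <- match.arg(method)
  data <- if (inherits(stack, "simulated_series")) stack$data else stack
  if (length(dim(data)) != 3) stop("'stack' must be rows x columns x echoes")
  if (is.list(masks)) masks <- Reduce(`|`, masks)
  if (!any(masks)) stop("background masks select no voxels")
  ne <- dim(data)[3]
  vals <- as.vector(apply(data, 3, function(sl) sl[masks]))
  sigma <- if (method == "second_moment") sqrt(mean(vals^2) / 2)
           else mean(vals) / sqrt(pi / 2)
  structure(list(sigma = sigma, n_voxels = sum(masks), method = method),
            class = "noise_estimate")
}

#' Fitting options for the T2* estimators
#'
#' @param t2_bounds Box constraints on T2* (ms).
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param tol Relative parameter-change convergence tolerance.
#' @param init_snr_floor Echoes with magnitude above `init_snr_floor * sigma`
#'   enter the log-linear initialiser; with fewer than 3 such echoes the
#'   fallback initial guess `(max magnitude, delta_te * n_e / 2)` is used.
#' @param noise_model `"rician"` (default) or `"gaussian"` (plain least
#'   squares regardless of sigma).
#' @return A list of options.
#' @export
fit_options <- function(t2_bounds = c(1, 1000), max_iter = 200, tol = 1e-10,
                        init_snr_floor = 2, noise_model = c("rician", "gaussian")) {
  list(t2_bounds = t2_bounds, max_iter = max_iter, tol = tol,
       init_snr_floor = init_snr_floor, noise_model = match.arg(noise_model))
}

# Vectorised log-linear initialisation. M: voxels x echoes.
.init_loglin <- function(M, te, sigma, opts) {
  ne <- length(te)
  W <- (M > opts$init_snr_floor * sigma) * 1
  okn <- rowSums(W) >= 3
  L <- log(pmax(M, 1e-300))
  sw <- rowSums(W)
  sx <- as.vector(W %*% te); sxx <- as.vector(W %*% te^2)
  sy <- rowSums(W * L); sxy <- as.vector((W * L) %*% te)
  den <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / ifelse(abs(den) > 1e-12, den, 1)
  inter <- (sy - slope * sx) / pmax(sw, 1)
  dte <- mean(diff(te))
  t2 <- ifelse(okn & slope < 0, -1 / slope, dte * ne / 2)
  a <- ifelse(okn & slope < 0, exp(pmin(inter, 300)), apply(M, 1, max))
  t2 <- pmin(pmax(t2, opts$t2_bounds[1]), opts$t2_bounds[2])
  list(a = pmax(a, 1e-12), t2 = t2)
}

#' Fit T2* to many voxel series at once
#'
#' Vectorised Rician maximum-likelihood (or Gaussian least-squares)
#' mono-exponential fit, one row of `M` per voxel. This is the numerical
#' engine behind [fit_t2star_rician()] and [fit_t2star_map()]; all voxels
#' are iterated simultaneously.
#'
#' @param M Magnitude matrix, voxels x echoes.
#' @param train An [echo_train()] matching the columns of `M`.
#' @param sigma Known noise standard deviation (0 implies least squares).
#' @param options See [fit_options()].
#' @return A data.frame with one row per voxel: `amplitude`, `t2_star`,
#'   `converged`, `n_iter`, `objective` (negative log-likelihood for the
#'   Rician model, residual sum of squares for the Gaussian one).
#' @export
fit_t2star_batch <- function(M, train, sigma, options = fit_options()) {
  stopifnot(inherits(train, "echo_train"))
  M <- base::matrix(M, ncol = train$n_e)
  te <- train$te
  ne <- length(te)
  if (ne < 3) stop("at least 3 echoes are required for a two-parameter fit")
  if (sigma < 0) stop("'sigma' must be non-negative")
  opts <- options
  rician <- opts$noise_model == "rician" && sigma > 0
  nvox <- nrow(M)
  ini <- .init_loglin(M, te, sigma, opts)
  a <- ini$a; t2 <- ini$t2
  TE <- base::matrix(te, nvox, ne, byrow = TRUE)
  conv <- rep(FALSE, nvox)
  iter_done <- rep(0L, nvox)
  s2 <- sigma^2
  for (it in seq_len(opts$max_iter)) {
    E <- exp(-TE / t2)            # column-major recycling: t2 varies by row
    nu <- a * E
    Mt <- if (rician) M * bessel_i1i0_ratio(M * nu / s2) else M
    r <- Mt - nu
    dA <- E
    dT <- a * TE / t2^2 * E
    g1 <- rowSums(r * dA); g2 <- rowSums(r * dT)
    h11 <- rowSums(dA * dA); h12 <- rowSums(dA * dT); h22 <- rowSums(dT * dT)
    det <- h11 * h22 - h12^2
    ok <- is.finite(det) & det > 1e-300
    det[!ok] <- 1
    stepA <- (h22 * g1 - h12 * g2) / det
    stepT <- (-h12 * g1 + h11 * g2) / det
    stepA[!ok] <- 0; stepT[!ok] <- 0
    # damp the T2 step to half the current value to keep iterates positive
    damp <- pmin(1, 0.5 * t2 / pmax(abs(stepT), 1e-300))
    a_new <- pmax(a + damp * stepA, 1e-12)
    t2_new <- pmin(pmax(t2 + damp * stepT, opts$t2_bounds[1]), opts$t2_bounds[2])
    delta <- pmax(abs(t2_new - t2) / t2, abs(a_new - a) / pmax(a, 1e-12))
    newly <- !conv & (delta < opts$tol)
    iter_done[!conv] <- it
    conv <- conv | newly
    a <- a_new; t2 <- t2_new
    if (all(conv)) break
  }
  at_bound <- t2 <= opts$t2_bounds[1] + 1e-9 | t2 >= opts$t2_bounds[2] - 1e-9
  E <- exp(-TE / t2); nu <- a * E
  objective <- if (rician)
    -rowSums(base::matrix(rician_loglik(as.vector(M), as.vector(nu), sigma),
                          nvox, ne))
  else rowSums((M - nu)^2)
  data.frame(amplitude = a, t2_star = t2,
             converged = conv & !at_bound, n_iter = iter_done,
             objective = objective)
}

#' Rician-likelihood T2* fit of a single voxel series
#'
#' Maximises the Rician log-likelihood of the observed magnitudes under the
#' mono-exponential model `nu_n = A exp(-TE_n / T2*)` with known `sigma`.
#' With `sigma = 0` the fit degenerates to ordinary least squares.
#' Initialisation is a log-linear regression on echoes above
#' `init_snr_floor * sigma`. Non-convergence is flagged, not raised.
#'
#' @param train An [echo_train()] (>= 3 echoes).
#' @param magnitudes Observed magnitude series, same length as the train.
#' @param sigma Known noise standard deviation (>= 0).
#' @param options See [fit_options()].
#' @return An object of class `fit_result`: `amplitude` (the product of
#'   spin density and steady-state factor -- the only amplitude
#'   identifiable from magnitude data), `t2_star` (ms), `converged`,
#'   `n_iter`, `objective`.
#' @export
fit_t2star_rician <- function(train, magnitudes, sigma, options = fit_options()) {
  if (length(magnitudes) != train$n_e)
    stop("'magnitudes' length must equal the echo count")
  res <- fit_t2star_batch(base::matrix(magnitudes, 1), train, sigma, options)
  structure(as.list(res[1, ]), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> A = %.4g, T2* = %.3f ms (%s, %d iter)\n",
              x$amplitude, x$t2_star,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Voxelwise T2* map fit
#'
#' Applies the Rician mono-exponential fit to every voxel of a magnitude
#' stack inside a foreground mask. Voxels outside the mask carry `NA`
#' sentinels. By default the mask keeps voxels whose first-echo magnitude
#' exceeds `5 * sigma` (all nonzero voxels when `sigma = 0`).
#'
#' @param stack A [simulate_series()] result or 3-D magnitude array.
#' @param train An [echo_train()]; taken from the series when omitted.
#' @param sigma Known noise standard deviation.
#' @param mask Optional logical matrix restricting the fit.
#' @param options See [fit_options()].
#' @return A list with matrices `t2_star`, `amplitude`, `converged` (NA
#'   outside the mask) and a `diagnostics` data.frame of per-voxel results
#'   (row order follows `which(mask)`).
#' @export
fit_t2star_map <- function(stack, train = NULL, sigma, mask = NULL,
                           options = fit_options()) {
  data <- if (inherits(stack, "simulated_series")) stack$data else stack
  if (is.null(train) && inherits(stack, "simulated_series")) train <- stack$train
  stopifnot(inherits(train, "echo_train"), length(dim(data)) == 3,
            dim(data)[3] == train$n_e)
  nr <- dim(data)[1]; nc <- dim(data)[2]
  if (is.null(mask)) {
    first <- data[, , 1]
    mask <- if (sigma > 0) first > 5 * sigma else first > 0
  }
  idx <- which(mask)
  if (length(idx) == 0) stop("mask selects no voxels")
  M <- base::matrix(data, nr * nc, train$n_e)[idx, , drop = FALSE]
  fit <- fit_t2star_batch(M, train, sigma, options)
  t2map <- base::matrix(NA_real_, nr, nc)
  amap <- base::matrix(NA_real_, nr, nc)
  cmap <- base::matrix(NA, nr, nc)
  t2map[idx] <- fit$t2_star
  amap[idx] <- fit$amplitude
  cmap[idx] <- fit$converged
  list(t2_star = t2map, amplitude = amap, converged = cmap, diagnostics = fit)
}
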