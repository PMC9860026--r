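# Iterative correction of parity-dependent amplitude modulation in
# bipolar echo trains.
#
# Procedure per iteration: (1) fit (A, T2*) to all echoes; (2) synthesise
# the model signal from the fit; (3) estimate the odd/even amplitude
# factors as the median measured/synthesised ratio per parity, normalised
# to geometric mean 1 (the common scale is not identifiable and is
# absorbed by the amplitude); (4) divide the data by the factors. Stops
# when max |g - 1| < tol or after max_iter iterations; the returned
# factors are the product over iterations.

#' Correct parity-dependent amplitude modulation
#'
#' Applies the iterative synthesise-and-compare correction to bipolar
#' multi-echo magnitude data. Requires a train with alternating parity:
#' on a constant-parity (monopolar or evenly-strided) train the odd/even
#' factors are not identifiable and an error is raised.
#'
#' @param stack A magnitude matrix (voxels x echoes), a single magnitude
#'   series, or a [simulate_series()] result (then `mask` selects voxels;
#'   defaults to first-echo magnitude > 5 sigma).
#' @param train An [echo_train()] with alternating parity and >= 4 echoes;
#'   taken from the series when omitted.
#' @param sigma Known noise standard deviation for the Rician fits.
#' @param max_iter Maximum number of correction iterations.
#' @param tol Convergence tolerance on max |g - 1| per iteration.
#' @param mode `"voxel"` estimates factors per voxel (default, mirroring
#'   voxelwise fitting); `"pooled"` estimates a single odd/even pair from
#'   all voxels.
#' @param mask Optional logical matrix when `stack` is a series.
#' @param options See [fit_options()].
#' @return An object of class `am_correction_result`: `modulation` (a
#'   [parity_modulation()] for pooled mode, or a data.frame of per-voxel
#'   factors), `corrected` (same shape as the input data), `fit` (final
#'   batch fit), `n_iter`, `converged`.
#' @export
correct_amplitude_modulation <- function(stack, train = NULL, sigma,
                                         max_iter = 10, tol = 1e-4,
                                         mode = c("voxel", "pooled"),
                                         mask = NULL, options = fit_options()) {
  mode <- match.arg(mode)
  series_in <- inherits(stack, "simulated_series")
  if (series_in) {
    if (is.null(train)) train <- stack$train
    data <- stack$data
    nr <- dim(data)[1]; nc <- dim(data)[2]
    if (is.null(mask)) {
      first <- data[, , 1]
      mask <- if (sigma > 0) first > 5 * sigma else first > 0
    }
    idx <- which(mask)
    M <- base::matrix(data, nr * nc, train$n_e)[idx, , drop = FALSE]
  } else {
    M <- base::matrix(stack, ncol = train$n_e)
  }
  stopifnot(inherits(train, "echo_train"))
  if (train$n_e < 4) stop("amplitude-modulation correction needs at least 4 echoes")
  parities <- unique(train$parity)
  if (length(parities) < 2)
    stop("not applicable: the train has constant readout parity, ",
         "odd/even modulation factors are not identifiable")
  odd <- train$parity == "odd"
  nvox <- nrow(M)
  g_odd <- rep(1, nvox); g_even <- rep(1, nvox)
  Mc <- M
  converged <- FALSE
  fit <- NULL
  it <- 0L
  for (it in seq_len(max_iter)) {
    fit <- fit_t2star_batch(Mc, train, sigma, options)
    TE <- base::matrix(train$te, nvox, train$n_e, byrow = TRUE)
    nu <- fit$amplitude * exp(-TE / fit$t2_star)
    ratio <- Mc / pmax(nu, 1e-300)
    if (mode == "voxel") {
      ro <- apply(ratio[, odd, drop = FALSE], 1, stats::median)
      re <- apply(ratio[, !odd, drop = FALSE], 1, stats::median)
    } else {
      ro <- rep(stats::median(ratio[, odd]), nvox)
      re <- rep(stats::median(ratio[, !odd]), nvox)
    }
    s <- sqrt(ro * re)
    ro <- ro / s; re <- re / s
    Mc[, odd] <- Mc[, odd] / ro
    Mc[, !odd] <- Mc[, !odd] / re
    g_odd <- g_odd * ro; g_even <- g_even * re
    if (max(abs(c(ro, re) - 1)) < tol) { converged <- TRUE; break }
  }
  fit <- fit_t2star_batch(Mc, train, sigma, options)
  modulation <- if (mode == "pooled")
    parity_modulation(g_odd[1], g_even[1])
  else data.frame(g_odd = g_odd, g_even = g_even)
  corrected <- Mc
  if (series_in) {
    out <- stack$data
    flat <- base::matrix(out, nr * nc, train$n_e)
    flat[idx, ] <- Mc
    corrected <- array(flat, dim(stack$data))
  }
  structure(list(modulation = modulation, corrected = corrected, fit = fit,
                 n_iter = it, converged = converged),
            class = "am_correction_result")
}
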