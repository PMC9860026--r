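# Simulation of multi-echo magnitude image stacks and echo subsampling.

#' Simulate a multi-echo magnitude image stack from a phantom
#'
#' Every voxel follows the noiseless spoiled-GRE signal of its region's
#' tissue parameters (optionally scaled by parity-dependent amplitude
#' modulation), then complex Gaussian noise of standard deviation
#' `acq$sigma` is added per channel and the modulus taken. Background
#' voxels (label 0) carry pure noise magnitude. The result is bit-identical
#' for a fixed seed.
#'
#' @param phantom A [build_default_phantom()] object.
#' @param acq An [acquisition_params()] (its `sigma` is the noise level).
#' @param train An [echo_train()].
#' @param mod Optional [parity_modulation()] applied per echo parity.
#' @param seed Integer seed for the noise draw (`NULL` uses the current RNG
#'   state).
#' @return An object of class `simulated_series`: `data` (rows x columns x
#'   echoes magnitude array), `train`, `sigma_true`, `seed`, `provenance`.
#' @export
simulate_series <- function(phantom, acq, train, mod = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(acq, "acquisition_params"),
            inherits(train, "echo_train"))
  if (!is.null(seed))
    return(with_seed(seed, {
      out <- simulate_series(phantom, acq, train, mod = mod, seed = NULL)
      out$seed <- seed
      out
    }))
  nr <- phantom$matrix[1]; nc <- phantom$matrix[2]; ne <- train$n_e
  # per-region complex signal, rows = region id
  sig <- t(vapply(phantom$regions$roi, function(k) {
    s <- noiseless_signal(region_tissue(phantom, k), acq, train)
    if (!is.null(mod)) s <- apply_parity_modulation(s, train$parity, mod)
    s
  }, complex(ne)))
  lab <- as.vector(phantom$label_map)
  nvox <- nr * nc
  clean <- base::matrix(0 + 0i, nvox, ne)
  fg <- lab > 0L
  clean[fg, ] <- sig[lab[fg], , drop = FALSE]
  s <- acq$sigma
  mag <- if (s > 0) {
    sqrt((Re(clean) + stats::rnorm(nvox * ne, 0, s))^2 +
         (Im(clean) + stats::rnorm(nvox * ne, 0, s))^2)
  } else Mod(clean)
  structure(list(data = array(mag, c(nr, nc, ne)), train = train,
                 sigma_true = s, seed = seed,
                 provenance = list(alpha = acq$alpha, tr = acq$tr,
                                   scheme = train$scheme)),
            class = "simulated_series")
}

#' @export
print.simulated_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<simulated_series> %d x %d x %d echoes, sigma %.4g%s\n",
              d[1], d[2], d[3], x$sigma_true,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Simulate independent voxel decay curves
#'
#' Monte-Carlo helper: `n_voxels` independent realisations of the magnitude
#' decay of a single tissue under the given acquisition, as a matrix with
#' one row per voxel. Statistically equivalent to sampling a uniform region
#' of [simulate_series()].
#'
#' @param tissue A [tissue_params()].
#' @param acq An [acquisition_params()].
#' @param train An [echo_train()].
#' @param n_voxels Number of independent realisations.
#' @param mod Optional [parity_modulation()].
#' @param seed Optional integer seed.
#' @return Magnitude matrix `n_voxels` x `train$n_e`.
#' @export
simulate_voxels <- function(tissue, acq, train, n_voxels, mod = NULL, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, simulate_voxels(tissue, acq, train, n_voxels, mod)))
  s0 <- noiseless_signal(tissue, acq, train)
  if (!is.null(mod)) s0 <- apply_parity_modulation(s0, train$parity, mod)
  ne <- train$n_e
  clean <- base::matrix(s0, n_voxels, ne, byrow = TRUE)
  s <- acq$sigma
  if (s == 0) return(Mod(clean))
  sqrt((Re(clean) + stats::rnorm(n_voxels * ne, 0, s))^2 +
       (Im(clean) + stats::rnorm(n_voxels * ne, 0, s))^2)
}

#' Keep the first n echoes of a simulated series
#'
#' Retrospective TE-range truncation: echoes `1..n` are kept with their
#' echo times and parity labels.
#'
#' @param series A [simulate_series()] result.
#' @param n Number of leading echoes to keep.
#' @return A `simulated_series` with `n` echoes.
#' @export
select_first_n <- function(series, n) {
  stopifnot(inherits(series, "simulated_series"))
  if (n < 1 || n > series$train$n_e) stop("'n' out of range")
  series$data <- series$data[, , seq_len(n), drop = FALSE]
  series$train <- first_n_echoes(series$train, n)
  series
}

#' Keep every n-th echo of a simulated series
#'
#' Retrospective echo-spacing dilution: keeps echoes `1, 1+n, 1+2n, ...`,
#' multiplying the effective echo spacing by `n`. Parity labels are
#' inherited, so an even stride on a bipolar series yields constant parity
#' (amplitude-modulation correction then no longer applies).
#'
#' @param series A [simulate_series()] result.
#' @param n Stride (>= 1).
#' @return A subsampled `simulated_series`.
#' @export
select_every_nth <- function(series, n) {
  stopifnot(inherits(series, "simulated_series"))
  if (n < 1) stop("'n' must be at least 1")
  idx <- seq(1L, series$train$n_e, by = as.integer(n))
  series$data <- series$data[, , idx, drop = FALSE]
  series$train <- every_nth_echo(series$train, n)
  series
}

#' Write a simulated series as NIfTI plus JSON sidecar
#'
#' The magnitude stack is stored as one 3-D NIfTI volume (echo as the third
#' axis); the echo train, noise level, seed and provenance go into a JSON
#' sidecar at `<prefix>.json`.
#'
#' @param series A [simulate_series()] result.
#' @param prefix Output path prefix (without extension).
#' @return The NIfTI path, invisibly.
#' @export
write_series <- function(series, prefix) {
  stopifnot(inherits(series, "simulated_series"))
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(series$data), nii)
  side <- list(te_ms = series$train$te, parity = series$train$parity,
               scheme = series$train$scheme, sigma = series$sigma_true,
               seed = series$seed, provenance = series$provenance)
  jsonlite::write_json(side, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(nii)
}

#' Read a multi-echo magnitude series written by [write_series()]
#'
#' Also accepts real multi-echo magnitude data stored in the same dialect
#' (3-D NIfTI, echo on the third axis, JSON sidecar with `te_ms` and
#' `parity`).
#'
#' @param prefix Path prefix used when writing.
#' @return A `simulated_series`.
#' @export
read_series <- function(prefix) {
  vol <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  train <- echo_train(side$te_ms, side$parity, scheme = side$scheme)
  structure(list(data = unclass(vol)[, , , drop = FALSE], train = train,
                 sigma_true = side$sigma,
                 seed = if (is.null(side$seed)) NA_integer_ else side$seed,
                 provenance = side$provenance),
            class = "simulated_series")
}
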