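# Echo-train timing for monopolar and bipolar multi-echo GRE readouts.
#
# Times are milliseconds throughout; bandwidths are Hz. A "monopolar" train
# acquires every echo under the same readout-gradient polarity, with a
# fly-back gradient (duration t_fb) between echoes; a "bipolar" train
# alternates polarity and omits the fly-back, which shortens the echo
# spacing to t_acq + 2 t_ramp.

#' Gradient timing parameters of a multi-echo readout
#'
#' Container for the sequence timing that determines the echo-train schedule:
#' the preparation time before the first acquisition window (RF pulse,
#' slice-selection, phase-encoding and dephasing gradients), the gradient
#' ramp time, and the fly-back gradient duration used by monopolar readouts.
#'
#' @param t_prep Preparation time before the first acquisition window (ms).
#' @param t_ramp Gradient ramp-up/ramp-down time (ms).
#' @param t_fb Fly-back gradient duration (ms). Only monopolar trains use it;
#'   `t_fb = 0` makes the monopolar schedule coincide with the bipolar one.
#' @param raster Timing granularity used when rounding derived durations (ms).
#' @return An object of class `gradient_timing`.
#' @seealso [te_schedule()], [timing_from_protocol()]
#' @export
gradient_timing <- function(t_prep, t_ramp, t_fb = 0, raster = 0.01) {
  vals <- c(t_prep = t_prep, t_ramp = t_ramp, t_fb = t_fb, raster = raster)
  if (any(!is.finite(vals)) || any(vals[c("t_prep", "t_ramp", "t_fb")] < 0))
    stop("gradient timing components must be finite and non-negative")
  if (raster <= 0) stop("'raster' must be positive")
  structure(as.list(vals), class = "gradient_timing")
}

#' Acquisition-window duration for one echo
#'
#' The time needed to sample one echo is the number of readout samples
#' divided by the total receiver bandwidth, rounded *up* to the scanner's
#' timing raster.
#'
#' @param n_x Number of readout samples per echo.
#' @param bw_total Total receiver bandwidth (Hz), i.e. bandwidth per pixel
#'   times the readout matrix size.
#' @param raster Rounding granularity (ms).
#' @return Acquisition-window duration in ms.
#' @examples
#' acquisition_time(240, 801 * 240)  # 1.25 ms
#' @export
acquisition_time <- function(n_x, bw_total, raster = 0.01) {
  if (n_x < 1) stop("'n_x' must be at least 1")
  if (bw_total <= 0 || raster <= 0) stop("'bw_total' and 'raster' must be positive")
  t_ms <- 1000 * n_x / bw_total
  # epsilon guards against an exact multiple landing just above the grid
  ceiling(t_ms / raster - 1e-9) * raster
}

#' Construct an echo train
#'
#' Low-level constructor validating the echo-time schedule and its per-echo
#' readout-polarity parity labels. Most users will build trains with
#' [te_schedule()] or [train_from_protocol()].
#'
#' @param te Strictly increasing echo times (ms).
#' @param parity Character vector of per-echo polarity labels, `"odd"` or
#'   `"even"`; same length as `te`. Monopolar trains have constant parity,
#'   bipolar trains alternate.
#' @param scheme Optional readout scheme label carried for provenance.
#' @return An object of class `echo_train` with fields `te`, `parity`,
#'   `n_e`, `delta_te` (NA when spacing is non-uniform) and `scheme`.
#' @export
echo_train <- function(te, parity, scheme = NULL) {
  if (length(te) < 1) stop("an echo train needs at least one echo")
  if (any(diff(te) <= 0)) stop("'te' must be strictly increasing")
  if (length(parity) != length(te)) stop("'te' and 'parity' lengths differ")
  if (!all(parity %in% c("odd", "even"))) stop("parity labels must be 'odd' or 'even'")
  d <- diff(te)
  delta_te <- if (length(d) == 0L) NA_real_
              else if (max(d) - min(d) < 1e-6) mean(d) else NA_real_
  structure(list(te = as.numeric(te), parity = as.character(parity),
                 n_e = length(te), delta_te = delta_te, scheme = scheme),
            class = "echo_train")
}

#' @export
print.echo_train <- function(x, ...) {
  cat(sprintf("<echo_train> %d echoes, TE %.2f..%.2f ms, dTE %s ms%s\n",
              x$n_e, x$te[1], x$te[x$n_e],
              if (is.na(x$delta_te)) "non-uniform" else sprintf("%.3f", x$delta_te),
              if (is.null(x$scheme)) "" else paste0(" (", x$scheme, ")")))
  invisible(x)
}

#' Echo-time schedule for a readout scheme
#'
#' Builds the TE schedule from gradient timing. For both schemes the n-th
#' echo is centred at `t_prep + (2n - 1)(t_acq/2 + t_ramp)`; monopolar
#' readouts additionally accumulate one fly-back duration per preceding
#' echo, so their spacing is `t_acq + 2 t_ramp + t_fb` against the bipolar
#' `t_acq + 2 t_ramp`.
#'
#' @param timing A [gradient_timing()] object.
#' @param t_acq Acquisition-window duration per echo (ms), see
#'   [acquisition_time()].
#' @param scheme `"monopolar"` or `"bipolar"`.
#' @param n_e Number of echoes (>= 1).
#' @return An [echo_train()].
#' @export
te_schedule <- function(timing, t_acq, scheme = c("monopolar", "bipolar"), n_e) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(timing, "gradient_timing"))
  if (n_e < 1) stop("'n_e' must be at least 1")
  n <- seq_len(n_e)
  te <- timing$t_prep + (2 * n - 1) * (t_acq / 2 + timing$t_ramp)
  if (scheme == "monopolar") te <- te + (n - 1) * timing$t_fb
  parity <- if (scheme == "monopolar") rep("odd", n_e)
            else c("odd", "even")[1 + (n + 1) %% 2]
  echo_train(te, parity, scheme = scheme)
}

#' Number of echoes fitting in a TE range
#'
#' Largest N such that `te_1 + (N - 1) * delta_te <= te_max`; the boundary
#' is inclusive, the convention that reproduces the published echo counts
#' (32/64 echoes at a 97 ms range and 14/27 at 43 ms for the TE1 = 3.84 ms,
#' dTE = 2.92/1.47 ms protocol).
#'
#' @param te_1 First echo time (ms).
#' @param delta_te Echo spacing (ms), positive.
#' @param te_max Upper TE limit (ms).
#' @return Integer echo count (0 when `te_max < te_1`).
#' @export
count_echoes <- function(te_1, delta_te, te_max) {
  if (delta_te <= 0) stop("'delta_te' must be positive")
  if (te_max < te_1) return(0L)
  as.integer(floor((te_max - te_1) / delta_te + 1e-9)) + 1L
}

#' Recover gradient timing from a printed protocol
#'
#' Inverts the echo-time equations so that a protocol reported only as
#' (TE1, monopolar dTE, bipolar dTE) can be replayed:
#' `t_ramp = (delta_te_bip - t_acq) / 2`, `t_fb = delta_te_mono -
#' delta_te_bip`, `t_prep = te_1 - t_acq/2 - t_ramp`. The decomposition is
#' one consistent choice, not necessarily the scanner's.
#'
#' @param te_1 First echo time (ms).
#' @param delta_te_mono Monopolar echo spacing (ms).
#' @param delta_te_bip Bipolar echo spacing (ms).
#' @param t_acq Acquisition-window duration (ms).
#' @return A [gradient_timing()] that round-trips through [te_schedule()].
#' @export
timing_from_protocol <- function(te_1, delta_te_mono, delta_te_bip, t_acq) {
  if (!(delta_te_mono >= delta_te_bip && delta_te_bip >= t_acq))
    stop("inconsistent protocol: need delta_te_mono >= delta_te_bip >= t_acq")
  t_ramp <- (delta_te_bip - t_acq) / 2
  t_fb <- delta_te_mono - delta_te_bip
  t_prep <- te_1 - t_acq / 2 - t_ramp
  if (t_prep < 0) stop("inconsistent protocol: derived t_prep is negative")
  gradient_timing(t_prep = t_prep, t_ramp = t_ramp, t_fb = t_fb)
}

#' Bandwidth scaling of image noise
#'
#' The complex-channel noise standard deviation scales with the square root
#' of the receiver bandwidth: `sigma_0 * sqrt(bw / bw_0)`.
#'
#' @param sigma_0 Noise standard deviation at the reference bandwidth (a.u.).
#' @param bw Bandwidth of interest (Hz); per-pixel and total bandwidth give
#'   the same ratio provided both arguments use the same convention.
#' @param bw_0 Reference bandwidth (Hz).
#' @return Scaled noise standard deviation.
#' @export
noise_sigma <- function(sigma_0, bw, bw_0) {
  if (sigma_0 <= 0 || bw <= 0 || bw_0 <= 0) stop("all arguments must be positive")
  sigma_0 * sqrt(bw / bw_0)
}

#' Echo train directly from (TE1, dTE) protocol numbers
#'
#' Convenience builder used when replaying published protocols: echoes at
#' `te_1 + (0:(n_e-1)) * delta_te`, with as many echoes as fit in `te_max`
#' (inclusive) unless `n_e` is given explicitly.
#'
#' @param te_1 First echo time (ms).
#' @param delta_te Echo spacing (ms).
#' @param scheme `"monopolar"` or `"bipolar"` (sets the parity pattern).
#' @param te_max Upper TE limit (ms); ignored when `n_e` is supplied.
#' @param n_e Optional explicit echo count.
#' @return An [echo_train()].
#' @export
train_from_protocol <- function(te_1, delta_te, scheme = c("monopolar", "bipolar"),
                                te_max = NULL, n_e = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(n_e)) {
    if (is.null(te_max)) stop("supply either 'te_max' or 'n_e'")
    n_e <- count_echoes(te_1, delta_te, te_max)
    if (n_e < 1) stop("no echoes fit below 'te_max'")
  }
  n <- seq_len(n_e)
  parity <- if (scheme == "monopolar") rep("odd", n_e)
            else c("odd", "even")[1 + (n + 1) %% 2]
  echo_train(te_1 + (n - 1) * delta_te, parity, scheme = scheme)
}

#' Keep the first n echoes of a train
#' @param train An [echo_train()].
#' @param n Number of leading echoes to keep (1 <= n <= n_e).
#' @return The truncated [echo_train()].
#' @export
first_n_echoes <- function(train, n) {
  stopifnot(inherits(train, "echo_train"))
  if (n < 1 || n > train$n_e) stop("'n' out of range")
  echo_train(train$te[seq_len(n)], train$parity[seq_len(n)], scheme = train$scheme)
}

#' Keep every n-th echo of a train
#'
#' Keeps echoes 1, 1+n, 1+2n, ...; the effective echo spacing is multiplied
#' by `n` while parity labels are inherited from the source train. Note that
#' an even stride on a bipolar train yields constant parity.
#'
#' @param train An [echo_train()].
#' @param n Stride (>= 1).
#' @return The subsampled [echo_train()].
#' @export
every_nth_echo <- function(train, n) {
  stopifnot(inherits(train, "echo_train"))
  if (n < 1) stop("'n' must be at least 1")
  idx <- seq(1L, train$n_e, by = as.integer(n))
  echo_train(train$te[idx], train$parity[idx], scheme = train$scheme)
}

#' Published acquisition protocols
#'
#' The four printed protocols (receiver bandwidth per pixel 801, 718, 613
#' and 342 Hz) with their first echo times and monopolar/bipolar echo
#' spacings, read from the YAML preset file shipped with the package.
#'
#' @return A data.frame with one row per protocol: `name`, `bw_per_px_hz`,
#'   `matrix`, `n_x`, `te1_ms`, `delta_te_mono_ms`, `delta_te_bip_ms`,
#'   `te_max_ms`.
#' @export
protocol_presets <- function() {
  path <- system.file("extdata", "protocols.yaml", package = "met2star")
  raw <- yaml::read_yaml(path)$protocols
  out <- do.call(rbind, lapply(names(raw), function(nm) {
    data.frame(name = nm, as.data.frame(raw[[nm]]))
  }))
  rownames(out) <- NULL
  out
}

#' Build an echo train from a named protocol preset
#'
#' @param name Preset name as listed by [protocol_presets()] (e.g. `"bw801"`).
#' @param scheme `"monopolar"` or `"bipolar"`.
#' @param te_max Optional TE-range override (ms); defaults to the preset's.
#' @return An [echo_train()].
#' @export
preset_train <- function(name, scheme = c("monopolar", "bipolar"), te_max = NULL) {
  scheme <- match.arg(scheme)
  p <- protocol_presets()
  row <- p[p$name == name, ]
  if (nrow(row) != 1) stop("unknown protocol preset: ", name)
  dte <- if (scheme == "monopolar") row$delta_te_mono_ms else row$delta_te_bip_ms
  train_from_protocol(row$te1_ms, dte, scheme,
                      te_max = if (is.null(te_max)) row$te_max_ms else te_max)
}
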