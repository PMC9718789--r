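#' Dip of a two-emitter intensity distribution
#'
#' The dip is the intensity at the midpoint between two emitters divided by
#' the global maximum of the distribution. It is 1 when the midpoint is the
#' brightest point (unresolved or exactly flat-topped) and decreases toward 0
#' as the pair becomes resolved; by construction it is invariant to global
#' intensity scaling. The configuration must be symmetric about the grid
#' center: for a matrix the center pixel of an odd-sized grid, for a profile
#' the middle sample.
#'
#' @param x a numeric profile, matrix or [image_frame()] holding a symmetric
#'   two-emitter distribution centered on the grid.
#' @return The dip value in `[0, 1]`.
#' @examples
#' sc <- two_emitter_scene(3, sigma = 10)
#' dip(render_gaussian(sc, gaussian_psf(10)))
#' @export
dip <- function(x) {
  if (inherits(x, "image_frame") || is.matrix(x)) {
    m <- as_pixel_matrix(as_image_frame(x))
    d <- dim(m)
    if (any(d %% 2 == 0))
      stop("dip needs an odd-sized grid with a defined center pixel",
           call. = FALSE)
    center <- m[(d[1] + 1) / 2, (d[2] + 1) / 2]
    mx <- max(m)
  } else {
    v <- as.numeric(x)
    if (length(v) %% 2 == 0)
      stop("dip needs an odd-length profile with a defined center sample",
           call. = FALSE)
    center <- v[(length(v) + 1) / 2]
    mx <- max(v)
  }
  if (mx <= 0)
    stop("dip undefined: all-zero distribution", call. = FALSE)
  center / mx
}

#' Dip-versus-separation curve for two Gaussian emitters
#'
#' For each separation (in multiples of the emitter standard deviation) the
#' two-emitter scene is rendered on a shared 2D grid, optionally processed
#' with single-frame MSSR, and the [dip()] of the result is recorded. With
#' `order = "DL"` the unprocessed (diffraction-limited) curve is returned.
#'
#' @param order `"DL"` for the unprocessed curve, or an integer MSSR order.
#' @param separations sorted separations in sigma multiples
#'   (default 0 to 4 by 0.05).
#' @param sigma emitter standard deviation in pixels (default 10).
#' @param params optional [mssr_params()]; defaults to `amp = 1`, no
#'   interpolation, `psf_fwhm` equal to the emitter FWHM
#'   `2 sqrt(2 log 2) sigma`.
#' @return A data.frame of class `dip_curve` with columns `separation`
#'   and `dip`, and an `order` attribute.
#' @examples
#' dc <- dip_curve("DL", separations = seq(0, 4, by = 0.5), sigma = 6)
#' resolution_limit(dc, "sparrow")
#' @export
dip_curve <- function(order = "DL", separations = seq(0, 4, by = 0.05),
                      sigma = 10, params = NULL) {
  if (is.unsorted(separations))
    stop("`separations` must be sorted ascending", call. = FALSE)
  process <- !identical(order, "DL")
  if (process && is.null(params))
    params <- mssr_params(amp = 1, psf_fwhm = 2 * sqrt(2 * log(2)) * sigma,
                          order = as.integer(order), interpolation = "none")
  psf <- gaussian_psf(sigma)
  dips <- vapply(separations, function(s) {
    fr <- render_gaussian(
      two_emitter_scene(s, sigma,
                        max_separation_in_sigma = max(separations, 4)), psf)
    if (process) fr <- sf_mssr(fr, params)
    dip(fr)
  }, numeric(1))
  structure(data.frame(separation = separations, dip = dips),
            order = if (process) params$order else "DL",
            class = c("dip_curve", "data.frame"))
}

#' Two-point resolution limit from a dip curve
#'
#' Extracts a resolution limit from a dip-versus-separation curve:
#' \describe{
#'   \item{sparrow}{the largest separation at which the dip still equals the
#'     distribution maximum (dip = 1, to within `flat_tol`) — the last flat
#'     point of the scan before the central dip first appears. Declared at
#'     the grid resolution of the curve.}
#'   \item{rayleigh}{the separation at which the dip first crosses a stated
#'     dip value (0.74 by default), linearly interpolated between grid
#'     points.}
#' }
#'
#' @param curve a [dip_curve()] (or data.frame with `separation`, `dip`).
#' @param criterion `"sparrow"` or `"rayleigh"`.
#' @param dip_value dip level defining the Rayleigh criterion (default 0.74).
#' @param flat_tol numeric tolerance below 1 still counted as flat.
#' @return The limit as a separation in the curve's units (sigma multiples).
#' @export
resolution_limit <- function(curve, criterion = c("sparrow", "rayleigh"),
                             dip_value = 0.74, flat_tol = 1e-6) {
  criterion <- match.arg(criterion)
  s <- curve$separation
  d <- curve$dip
  if (criterion == "sparrow") {
    drop_idx <- which(d < 1 - flat_tol)
    if (length(drop_idx) == 0L)
      stop("no dip < 1 in range: curve does not span the Sparrow crossing",
           call. = FALSE)
    i <- drop_idx[1]
    if (i == 1L)
      stop("curve starts below dip = 1: Sparrow boundary not spanned",
           call. = FALSE)
    return(s[i - 1L])
  }
  below <- which(d < dip_value)
  if (length(below) == 0L)
    stop(sprintf("no dip < %g in range: Rayleigh crossing not spanned",
                 dip_value), call. = FALSE)
  i <- below[1]
  if (i == 1L) return(s[1])
  s[i - 1] + (d[i - 1] - dip_value) / (d[i - 1] - d[i]) * (s[i] - s[i - 1])
}

#' Directly measured full width at half maximum
#'
#' Width between the two half-maximum crossings of a unimodal profile,
#' linearly interpolated between samples.
#'
#' @param profile numeric intensity profile, or a data.frame with columns
#'   `coord` and `intensity` as returned by [peak_profile()].
#' @param coords optional sample coordinates (defaults to 1 px spacing).
#' @return The FWHM in coordinate units.
#' @examples
#' x <- seq(-50, 50)
#' measure_fwhm(exp(-x^2 / 200), x)  # 2 sqrt(2 log 2) * 10
#' @export
measure_fwhm <- function(profile, coords = NULL) {
  pc <- as_profile(profile, coords)
  y <- pc$y; x <- pc$x
  h <- max(y) / 2
  i <- which.max(y)
  if (all(y[1:i] >= h) || all(y[i:length(y)] >= h))
    stop("no half-maximum crossing: profile flat or truncated", call. = FALSE)
  li <- max(which(y[1:i] < h))
  ri <- i - 1 + min(which(y[i:length(y)] < h))
  xl <- x[li] + (h - y[li]) / (y[li + 1] - y[li]) * (x[li + 1] - x[li])
  xr <- x[ri - 1] + (h - y[ri - 1]) / (y[ri] - y[ri - 1]) * (x[ri] - x[ri - 1])
  xr - xl
}

#' Gaussian sigma fitted to a profile
#'
#' Nonlinear least-squares fit of
#' `A * exp(-(x - x0)^2 / (2 sigma^2)) + baseline` to a single-peaked
#' profile (Levenberg-Marquardt, initial guesses from the peak and the
#' measured FWHM). Returns the fitted sigma in coordinate units.
#'
#' @inheritParams measure_fwhm
#' @param max_iter iteration cap for the optimizer.
#' @return Fitted sigma.
#' @examples
#' x <- seq(-60, 60)
#' fit_gaussian_sigma(exp(-x^2 / (2 * 100)), x)  # ~10
#' @export
fit_gaussian_sigma <- function(profile, coords = NULL, max_iter = 500) {
  pc <- as_profile(profile, coords)
  y <- pc$y; x <- pc$x
  i <- which.max(y)
  s0 <- tryCatch(measure_fwhm(y, x) / (2 * sqrt(2 * log(2))),
                 error = function(e) diff(range(x)) / 8)
  resid <- function(p) y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
  ft <- minpack.lm::nls.lm(
    par = c(A = max(y), x0 = x[i], sigma = s0, baseline = 0), fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  if (!ft$info %in% 1:4)
    stop("Gaussian fit did not converge: ", ft$message, call. = FALSE)
  abs(ft$par[["sigma"]])
}

as_profile <- function(profile, coords) {
  if (is.data.frame(profile)) {
    x <- profile$coord; y <- profile$intensity
  } else {
    y <- as.numeric(profile)
    x <- if (is.null(coords)) seq_along(y) - 1 else coords
  }
  if (length(x) != length(y)) stop("coords/profile length mismatch")
  list(x = x, y = y)
}

#' Signal-to-noise ratio and electron conversion
#'
#' `electrons()` converts camera counts to photoelectrons with the
#' calibration maps, `electrons = (counts - offset) / gain`. `snr()`
#' evaluates the shot-noise-limited signal-to-noise ratio in electron units,
#' `SNR = S / sqrt(S + I_b + N_r^2)` with `S` the signal electrons, `I_b`
#' the background electrons and `N_r` the readout noise (electrons RMS);
#' pixels with a zero denominator return 0 (dark pixel convention).
#'
#' @param signal_electrons signal in electrons (`QE` times signal photons).
#' @param background_electrons background in electrons.
#' @param readout_noise readout noise in electrons RMS.
#' @return `snr()`: dimensionless SNR; `electrons()`: electrons.
#' @examples
#' electrons(110, offset = 100, gain = 2)  # 5
#' snr(100, 0, 1)                          # 100 / sqrt(101)
#' @export
snr <- function(signal_electrons, background_electrons = 0, readout_noise = 0) {
  if (any(signal_electrons < 0) || any(background_electrons < 0) ||
      any(readout_noise < 0))
    stop("snr inputs must be non-negative", call. = FALSE)
  den <- sqrt(signal_electrons + background_electrons + readout_noise^2)
  ifelse(den == 0, 0, signal_electrons / den)
}

#' @rdname snr
#' @param counts raw camera counts.
#' @param offset,gain camera calibration maps (counts and counts/electron).
#' @export
electrons <- function(counts, offset, gain) {
  if (any(gain <= 0)) stop("`gain` must be > 0", call. = FALSE)
  (counts - offset) / gain
}

#' Reconstruction quality scores against a reference
#'
#' A simplified global fidelity measure for a super-resolved reconstruction
#' against its diffraction-limited reference: the reconstruction is
#' downscaled to the reference grid by block averaging, a linear intensity
#' map `a * x + b` is fitted by least squares, and two scores are reported:
#' `rsp`, the Pearson correlation of the downscaled reconstruction with the
#' reference (resolution-scaled Pearson), and `rse`, the root-mean-square
#' error after the linear mapping (resolution-scaled error), so scale and
#' offset differences are absorbed by `rse` but anti-correlation still shows
#' as `rsp = -1`. The full RSF-convolution machinery of the original
#' error-mapping method is intentionally not reproduced.
#'
#' @param reconstruction frame whose dimensions are an integer multiple of
#'   the reference's.
#' @param reference the reference frame.
#' @return A list with elements `rsp` (in `[-1, 1]`) and `rse` (>= 0, in
#'   reference intensity units).
#' @examples
#' r <- matrix(runif(16), 4, 4)
#' quality_scores(2 * r + 5, r)  # rsp = 1, rse = 0
#' @export
quality_scores <- function(reconstruction, reference) {
  rec <- as_pixel_matrix(as_image_frame(reconstruction))
  ref <- as_pixel_matrix(as_image_frame(reference))
  fac <- nrow(rec) / nrow(ref)
  if (fac != round(fac) || ncol(rec) / ncol(ref) != fac)
    stop("reconstruction dimensions must be an integer multiple of reference",
         call. = FALSE)
  if (sd(ref) == 0)
    stop("undefined correlation: constant reference", call. = FALSE)
  down <- block_mean(rec, as.integer(fac))
  x <- as.numeric(down); y <- as.numeric(ref)
  ab <- coef(stats::lm.fit(cbind(1, x), y))
  mapped <- ab[1] + ab[2] * x
  rse <- sqrt(mean((mapped - y)^2))
  # correlation of the (unmapped) downscaled reconstruction with the
  # reference: the fitted map absorbs scale and offset in RSE only, so an
  # anti-correlated reconstruction reports RSP = -1, not +1
  rsp <- if (sd(x) == 0) 0 else cor(x, y)
  list(rsp = unname(rsp), rse = unname(rse))
}

block_mean <- function(m, fac) {
  if (fac == 1L) return(m)
  nr <- nrow(m) / fac
  nc <- ncol(m) / fac
  # average fac x fac blocks via two folds
  rows <- rowsum(m, rep(seq_len(nr), each = fac)) / fac
  t(rowsum(t(rows), rep(seq_len(nc), each = fac)) / fac)
}

#' @rdname dip_curve
#' @param ... passed to `utils::write.csv`.
#' @param path output CSV path.
#' @param x a `dip_curve`.
#' @export
write_dip_curve <- function(x, path, ...) {
  df <- as.data.frame(x)
  df$order <- attr(x, "order")
  utils::write.csv(df, path, row.names = FALSE, ...)
  invisible(path)
}
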