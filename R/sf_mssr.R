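#' Algebraic transformations turning a mean-shift field into an image
#'
#' Applies the four ordered stages that convert the raw mean-shift field into
#' a resolution-enhanced frame: (1) complement (negate) the field so that
#' emitter centers, where the mean shift is most negative, become maxima;
#' (2) clip negative values to zero — the "negative constraints", the valley
#' the complement creates between peak and tails, are removed; (3) min-max
#' normalize to `[0, 1]`; (4) weight by the reference image to restore the
#' raw intensity distribution. A degenerate normalization (field constant)
#' yields an all-zero frame with a warning.
#'
#' @param ms a [mean_shift()] field (or any matrix of the same shape as
#'   `reference`).
#' @param reference the working image the field was computed from.
#' @return An [image_frame()], non-negative, same shape as `reference`.
#' @export
apply_transforms <- function(ms, reference) {
  reference <- as_image_frame(reference)
  m <- unclass(ms)
  attributes(m) <- list(dim = dim(m))
  ref <- as_pixel_matrix(reference)
  if (!identical(dim(m), dim(ref)))
    stop("`ms` and `reference` must have the same shape", call. = FALSE)
  f <- -m                       # stage 1: complement
  f[f < 0] <- 0                 # stage 2: negative-constraint removal
  if (max(f) == min(f)) {       # stage 3 degenerate: constant field
    warning("degenerate normalization (constant field); returning zeros",
            call. = FALSE)
    return(image_frame(ref * 0, pixel_size = pixel_size(reference)))
  }
  f <- norm01(f)                # stage 3: min-max normalization
  image_frame(f * ref, pixel_size = pixel_size(reference))  # stage 4
}

#' Single-frame MSSR
#'
#' `sf_mssr0()` computes the order-0 transform of one frame: magnify by
#' `amp` (interpolation), compute the mean-shift field with neighborhood
#' radius `ceiling(amp * psf_fwhm / 2)` and range bandwidth equal to the
#' working-image intensity range, and apply the algebraic transformations
#' ([apply_transforms()]). The output of a single Gaussian emitter is
#' strictly narrower than its input.
#'
#' `sf_mssr()` iterates the procedure to higher orders. Writing `M^k` for
#' the order-k image (with `M^{-1}` the interpolated input), each iteration
#' forms the inter-order residual `D^k = M^{k-2} - M^{k-1}` (a doughnut
#' centered on each emitter), subtracts it from the current order, removes
#' the negative constraints, renormalizes, and restores intensity from a
#' geometric blend of the two preceding orders:
#' \deqn{M^k = \mathrm{minmax}\{(2 M^{k-1} - M^{k-2})_+\} \cdot
#'       (M^{k-1})^{1/4} (M^{k-2})^{3/4}.}
#' The per-order FWHM of a single emitter is non-increasing in the order.
#' All orders reuse the order-0 bandwidths.
#'
#' @param image an [image_frame()] or matrix.
#' @param params an [mssr_params()] object.
#' @return An [image_frame()] of `amp` times the input dimensions.
#' @examples
#' fr <- render_gaussian(single_emitter_scene(40), gaussian_psf(10))
#' p <- mssr_params(amp = 1, psf_fwhm = 23.55, order = 3,
#'                  interpolation = "none")
#' out <- sf_mssr(fr, p)
#' @export
sf_mssr0 <- function(image, params) {
  s <- mssr_stages(image, params)
  finish_frame(s$M0, params, s$ps)
}

#' @rdname sf_mssr0
#' @export
sf_mssr <- function(image, params) {
  series <- sf_mssr_series(image, params)
  series[[length(series)]]
}

#' @rdname sf_mssr0
#' @return `sf_mssr_series()` returns the list of frames for orders
#'   `0 .. params$order` computed in a single pass (the mean-shift field is
#'   computed once and shared by all orders).
#' @export
sf_mssr_series <- function(image, params) {
  s <- mssr_stages(image, params)
  Mp2 <- as_pixel_matrix(s$work)     # M^{k-2}, starts at M^{-1} = input
  Mp <- s$M0                         # M^{k-1}, starts at M^0
  out <- vector("list", params$order + 1L)
  out[[1L]] <- finish_frame(Mp, params, s$ps)
  if (params$order >= 1L) {
    for (k in seq_len(params$order)) {
      f <- 2 * Mp - Mp2              # current order minus the residual D^k
      f[f < 0] <- 0
      if (max(f) == min(f)) {
        warning("degenerate normalization at order ", k, "; returning zeros",
                call. = FALSE)
        Mk <- f * 0
      } else {
        Mk <- norm01(f) * Mp^0.25 * Mp2^0.75
      }
      Mp2 <- Mp
      Mp <- Mk
      out[[k + 1L]] <- finish_frame(Mk, params, s$ps)
    }
  }
  names(out) <- paste0("order", 0:params$order)
  out
}

# shared pipeline head: interpolation, mean shift, order-0 transforms
mssr_stages <- function(image, params) {
  if (!inherits(params, "mssr_params"))
    stop("`params` must be an mssr_params object", call. = FALSE)
  frame <- as_image_frame(image)
  work <- interpolate_frame(frame, params$amp, params$interpolation)
  h_s <- ms_radius(params)
  ms <- mean_shift(work, h_s = h_s, boundary = params$boundary)
  M0 <- as_pixel_matrix(apply_transforms(ms, work))
  list(work = work, M0 = M0, ps = pixel_size(work))
}

finish_frame <- function(m, params, ps) {
  if (params$mesh_minimization && params$amp > 1L)
    m <- .median3x3_cpp(m)
  image_frame(m, pixel_size = ps)
}
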