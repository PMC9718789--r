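#' Mean-shift field of an image
#'
#' Computes, for every pixel, the kernel-weighted local mean over a circular
#' spatial-range neighborhood minus the center value:
#' \deqn{MS(x) = \frac{\sum_{y \in N(x)} w_s(\|y-x\|)\, w_r(I(y)-I(x))\, I(y)}
#'                    {\sum_{y \in N(x)} w_s\, w_r} - I(x)}
#' with \eqn{N(x)} the disk of radius `h_s` (center pixel included), uniform
#' spatial weights by default, and Gaussian range weights
#' \eqn{w_r(\Delta)=\exp(-\Delta^2/(2 h_r^2))}. The field is the intensity-axis
#' component of the mean-shift vector: it is zero on constant images and
#' negative at strict local maxima, and its minimum over a Gaussian blob
#' coincides with the blob's peak.
#'
#' @param image an [image_frame()] or matrix.
#' @param h_s spatial bandwidth: neighborhood radius in pixels, >= 1 and
#'   smaller than the image.
#' @param h_r range bandwidth in intensity units; defaults to the global
#'   intensity range of `image` (which makes subsequent stages invariant to
#'   intensity rescaling). Use `Inf` to disable range weighting.
#' @param boundary `"mirror"` (default) or `"constant"` zero padding.
#' @param spatial `"uniform"` (default) or `"gaussian"` spatial weights
#'   (sd = `h_s / 2`, truncated at `h_s`).
#' @param include_center logical; keep the center pixel in the neighborhood
#'   sum (default TRUE).
#' @return A matrix of class `mean_shift_field` with attributes `h_s`, `h_r`.
#' @examples
#' g <- render_gaussian(single_emitter_scene(30), gaussian_psf(6))
#' ms <- mean_shift(g, h_s = 7)
#' which.min(ms) == which.max(as_pixel_matrix(g))
#' @export
mean_shift <- function(image, h_s, h_r = NULL,
                       boundary = c("mirror", "constant"),
                       spatial = c("uniform", "gaussian"),
                       include_center = TRUE) {
  boundary <- match.arg(boundary)
  spatial <- match.arg(spatial)
  frame <- as_image_frame(image)
  m <- as_pixel_matrix(frame)
  stopifnot_scalar(h_s, "h_s")
  if (h_s < 1 || h_s != round(h_s))
    stop("`h_s` must be an integer >= 1", call. = FALSE)
  if (2 * h_s + 1 > max(dim(m)) * 2)  # radius beyond any sensible support
    stop("`h_s` is larger than the image", call. = FALSE)
  rng <- diff(range(m))
  if (is.null(h_r)) h_r <- rng
  if (!is.infinite(h_r) && h_r < 0)
    stop("`h_r` must be positive (or Inf to disable range weighting)",
         call. = FALSE)
  if (rng == 0) {
    out <- m * 0             # constant image: weighted mean equals the constant
  } else {
    hr_eff <- if (is.infinite(h_r)) -1 else h_r   # <= 0 disables range kernel
    out <- .ms_field_cpp(m, as.integer(h_s), hr_eff,
                         boundary = if (boundary == "mirror") 0L else 1L,
                         gaussian_spatial = spatial == "gaussian",
                         include_center = include_center)
  }
  structure(out, h_s = h_s, h_r = h_r, class = c("mean_shift_field", "matrix"))
}
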