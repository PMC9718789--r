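#' MSSR processing parameters
#'
#' Bundles the parameters of a single-frame or temporal MSSR run. The two
#' parameters that carry physical meaning are `amp`, the digital magnification
#' applied by interpolation before kernel processing, and `psf_fwhm`, the full
#' width at half maximum of the system PSF in pixels of the *input* image;
#' together they set the mean-shift neighborhood radius
#' `ceiling(amp * psf_fwhm / 2)` on the working (magnified) grid.
#'
#' @param amp integer magnification factor, >= 1.
#' @param psf_fwhm PSF full width at half maximum in input-image pixels, > 0.
#' @param order MSSR order n >= 0 (number of refinement iterations).
#' @param interpolation interpolation used to magnify the input:
#'   `"bicubic"` (default for single-frame analysis), `"fourier"`
#'   (default for temporal analysis) or `"none"`.
#' @param boundary padding policy of the mean-shift kernel at the image
#'   border: `"mirror"` (default) or `"constant"` (zero padding).
#' @param mesh_minimization logical; apply a small median smoothing pass on
#'   the magnified grid to suppress interpolation-mesh periodicity. Off by
#'   default and without effect on default results.
#' @return An object of class `mssr_params`.
#' @examples
#' mssr_params(amp = 1, psf_fwhm = 3.48, order = 3)
#' @export
mssr_params <- function(amp = 1L, psf_fwhm, order = 0L,
                        interpolation = c("bicubic", "fourier", "none"),
                        boundary = c("mirror", "constant"),
                        mesh_minimization = FALSE) {
  interp_given <- !missing(interpolation)
  interpolation <- match.arg(interpolation)
  boundary <- match.arg(boundary)
  stopifnot_scalar(amp, "amp")
  stopifnot_scalar(psf_fwhm, "psf_fwhm", positive = TRUE)
  stopifnot_scalar(order, "order")
  if (amp < 1 || amp != round(amp))
    stop("`amp` must be an integer >= 1", call. = FALSE)
  if (order < 0 || order != round(order))
    stop("`order` must be an integer >= 0", call. = FALSE)
  structure(list(amp = as.integer(amp), psf_fwhm = psf_fwhm,
                 order = as.integer(order), interpolation = interpolation,
                 boundary = boundary,
                 mesh_minimization = isTRUE(mesh_minimization),
                 interp_given = interp_given),
            class = "mssr_params")
}

#' @export
print.mssr_params <- function(x, ...) {
  cat(sprintf(
    "<mssr_params> AMP = %d, FWHM of PSF = %g px, order = %d, %s interpolation, %s boundary%s\n",
    x$amp, x$psf_fwhm, x$order, x$interpolation, x$boundary,
    if (x$mesh_minimization) ", mesh minimization" else ""))
  invisible(x)
}

# neighborhood radius on the working grid
ms_radius <- function(params) as.integer(ceiling(params$amp * params$psf_fwhm / 2))
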