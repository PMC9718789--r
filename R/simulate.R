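#' Point-spread function specifications
#'
#' `gaussian_psf()` describes an isotropic Gaussian PSF
#' \eqn{\exp(-((x-x_c)^2+(y-y_c)^2)/(2\sigma^2))} with unit peak.
#' `bessel_psf()` describes the Airy-type diffraction pattern
#' \eqn{I_0 (2 J_1(\upsilon)/\upsilon)^2} with the dimensionless radial
#' coordinate \eqn{\upsilon = (2\pi/\lambda)(NA/n)\, q}, where q is the radial
#' distance to the emitter in the same length unit as the emission wavelength;
#' the removable singularity at \eqn{\upsilon = 0} takes the value \eqn{I_0}.
#'
#' @param sigma Gaussian standard deviation (px or nm, matching the scene
#'   grid), > 0.
#' @param I0 peak intensity of the Bessel pattern.
#' @param lambda_em emission wavelength in nm, > 0.
#' @param na numerical aperture, > 0.
#' @param n_medium refractive index of the medium, >= 1.
#' @return A PSF specification object.
#' @examples
#' gaussian_psf(sigma = 10)
#' bessel_psf(lambda_em = 525, na = 1.4)
#' @export
gaussian_psf <- function(sigma) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  structure(list(sigma = sigma), class = c("gaussian_psf", "psf_spec"))
}

#' @rdname gaussian_psf
#' @export
bessel_psf <- function(I0 = 1, lambda_em, na, n_medium = 1) {
  stopifnot_scalar(I0, "I0", positive = TRUE)
  stopifnot_scalar(lambda_em, "lambda_em", positive = TRUE)
  stopifnot_scalar(na, "na", positive = TRUE)
  stopifnot_scalar(n_medium, "n_medium")
  if (n_medium < 1) stop("`n_medium` must be >= 1", call. = FALSE)
  structure(list(I0 = I0, lambda_em = lambda_em, na = na,
                 n_medium = n_medium),
            class = c("bessel_psf", "psf_spec"))
}

#' Emitter scenes
#'
#' An emitter scene holds ground-truth fluorophore positions and amplitudes on
#' a pixel grid. Positions are 0-based pixel coordinates (x along columns,
#' y along rows; sub-pixel positions allowed) and must lie inside the field.
#'
#' `two_emitter_scene()` builds the canonical two-point-resolution scene: two
#' equal emitters on the horizontal midline, separated by
#' `separation_in_sigma * sigma` pixels and centered on the field center. The
#' field spans 4 scene sigmas beyond each emitter position at the widest
#' scan separation so that a whole 0-4 sigma separation scan shares one grid.
#'
#' @param emitters data.frame with columns `x`, `y`, `amplitude`.
#' @param width,height field size in pixels.
#' @param pixel_size physical pixel size in nm/px (default 1).
#' @return An `emitter_scene` object.
#' @examples
#' two_emitter_scene(2, sigma = 10)
#' @export
emitter_scene <- function(emitters, width, height, pixel_size = 1) {
  if (!is.data.frame(emitters) ||
      !all(c("x", "y", "amplitude") %in% names(emitters)))
    stop("`emitters` needs columns x, y, amplitude", call. = FALSE)
  if (nrow(emitters) == 0L)
    stop("empty scene: at least one emitter is required", call. = FALSE)
  if (any(emitters$amplitude <= 0))
    stop("emitter amplitudes must be > 0", call. = FALSE)
  if (any(emitters$x < 0 | emitters$x > width - 1 |
          emitters$y < 0 | emitters$y > height - 1))
    stop("emitter coordinates must lie inside the field", call. = FALSE)
  structure(list(emitters = emitters, width = as.integer(width),
                 height = as.integer(height), pixel_size = pixel_size),
            class = "emitter_scene")
}

#' @rdname emitter_scene
#' @param separation_in_sigma center-to-center distance in units of `sigma`,
#'   >= 0.
#' @param sigma emitter standard deviation in pixels.
#' @param amplitude common emitter amplitude.
#' @param max_separation_in_sigma widest separation of the scan this scene
#'   belongs to; fixes the field size so all scan points share one grid.
#' @export
two_emitter_scene <- function(separation_in_sigma, sigma, amplitude = 1,
                              pixel_size = 1, max_separation_in_sigma = 4) {
  stopifnot_scalar(separation_in_sigma, "separation_in_sigma")
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (separation_in_sigma < 0)
    stop("`separation_in_sigma` must be >= 0", call. = FALSE)
  d <- separation_in_sigma * sigma
  half_w <- ceiling((max_separation_in_sigma / 2 + 4) * sigma)
  half_h <- ceiling(4 * sigma)
  cx <- half_w; cy <- half_h       # field center, 0-based
  emitter_scene(
    data.frame(x = c(cx - d / 2, cx + d / 2), y = c(cy, cy),
               amplitude = amplitude),
    width = 2 * half_w + 1, height = 2 * half_h + 1, pixel_size = pixel_size)
}

#' @rdname emitter_scene
#' @param half_extent half field size in pixels (field is
#'   `2 * half_extent + 1` on a side with the emitter at the center pixel).
#' @export
single_emitter_scene <- function(half_extent, amplitude = 1, pixel_size = 1) {
  emitter_scene(
    data.frame(x = half_extent, y = half_extent, amplitude = amplitude),
    width = 2 * half_extent + 1, height = 2 * half_extent + 1,
    pixel_size = pixel_size)
}

#' @export
print.emitter_scene <- function(x, ...) {
  cat(sprintf("<emitter_scene> %d emitter(s) on a %d x %d px field (%g nm/px)\n",
              nrow(x$emitters), x$width, x$height, x$pixel_size))
  invisible(x)
}

#' Render an emitter scene through a point-spread function
#'
#' Samples the sum over emitters of `amplitude * PSF(distance to emitter)` at
#' every pixel center. A single unit-amplitude emitter at a pixel center
#' renders with value 1 there under either PSF model. For the Bessel model
#' the radial distance enters in nm via the scene pixel size.
#'
#' @param scene an [emitter_scene()].
#' @param spec a [gaussian_psf()] or [bessel_psf()] specification.
#' @return An [image_frame()] of size `height x width`.
#' @examples
#' sc <- single_emitter_scene(40)
#' fr <- render_gaussian(sc, gaussian_psf(10))
#' max(fr) # 1 at the emitter pixel
#' @export
render_gaussian <- function(scene, spec) {
  if (!inherits(spec, "gaussian_psf")) stop("`spec` must be a gaussian_psf")
  render_scene(scene, function(r2_px)
    exp(-r2_px / (2 * spec$sigma^2)))
}

#' @rdname render_gaussian
#' @export
render_bessel <- function(scene, spec) {
  if (!inherits(spec, "bessel_psf")) stop("`spec` must be a bessel_psf")
  k <- 2 * pi / spec$lambda_em
  a <- k * spec$na / spec$n_medium
  render_scene(scene, function(r2_px) {
    v <- a * sqrt(r2_px) * scene$pixel_size
    out <- ifelse(v == 0, spec$I0,
                  spec$I0 * (2 * besselJ(v, 1) / v)^2)
    out
  })
}

# shared rasterization: psf_fun maps squared pixel distance -> intensity
render_scene <- function(scene, psf_fun) {
  if (!inherits(scene, "emitter_scene")) stop("`scene` must be an emitter_scene")
  xs <- 0:(scene$width - 1)
  ys <- 0:(scene$height - 1)
  img <- matrix(0, scene$height, scene$width)
  for (e in seq_len(nrow(scene$emitters))) {
    dx2 <- (xs - scene$emitters$x[e])^2
    dy2 <- (ys - scene$emitters$y[e])^2
    img <- img + scene$emitters$amplitude[e] *
      psf_fun(outer(dy2, dx2, `+`))
  }
  image_frame(img, pixel_size = scene$pixel_size)
}

#' Blinking specification and synthetic blinking stacks
#'
#' `blinking_spec()` describes a PAINT-like stochastic emission sequence:
#' each emitter is independently ON in each frame with probability
#' `on_probability` (i.i.d. Bernoulli per frame, a deliberate simplification
#' of association/dissociation kinetics). `blinking_stack()` renders one
#' frame per time point from the subset of ON emitters and returns the stack
#' together with the ground-truth ON/OFF matrix. The same seed always yields
#' the same stack.
#'
#' @param n_frames number of frames, >= 1.
#' @param on_probability per-frame, per-emitter ON probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param on_states optional logical matrix (emitters x frames) overriding the
#'   random draw, e.g. to build deterministic anti-correlated sequences.
#' @return `blinking_stack()` returns a list with elements `stack` (an
#'   [image_stack()]) and `on_states` (logical matrix, emitters x frames).
#' @examples
#' sc <- two_emitter_scene(3, sigma = 5)
#' b <- blinking_stack(sc, gaussian_psf(5), blinking_spec(10, 0.5, seed = 1))
#' dim(b$on_states)
#' @export
blinking_spec <- function(n_frames, on_probability, seed = 1L) {
  stopifnot_scalar(n_frames, "n_frames")
  stopifnot_scalar(on_probability, "on_probability")
  if (n_frames < 1) stop("`n_frames` must be >= 1 (empty stack)", call. = FALSE)
  if (on_probability < 0 || on_probability > 1)
    stop("`on_probability` must be in [0, 1]", call. = FALSE)
  structure(list(n_frames = as.integer(n_frames),
                 on_probability = on_probability, seed = as.integer(seed)),
            class = "blinking_spec")
}

#' @rdname blinking_spec
#' @param scene an [emitter_scene()].
#' @param psf a PSF specification.
#' @param blink a `blinking_spec`.
#' @export
blinking_stack <- function(scene, psf, blink, on_states = NULL) {
  if (!inherits(blink, "blinking_spec")) stop("`blink` must be a blinking_spec")
  ne <- nrow(scene$emitters)
  if (is.null(on_states)) {
    on_states <- with_seed(blink$seed,
      matrix(runif(ne * blink$n_frames) < blink$on_probability,
             nrow = ne, ncol = blink$n_frames))
  }
  if (!is.matrix(on_states) || nrow(on_states) != ne ||
      ncol(on_states) != blink$n_frames)
    stop("`on_states` must be an emitters x frames logical matrix", call. = FALSE)
  render1 <- function(e) {
    sub <- scene
    sub$emitters <- scene$emitters[e, , drop = FALSE]
    as_pixel_matrix(if (inherits(psf, "gaussian_psf"))
      render_gaussian(sub, psf) else render_bessel(sub, psf))
  }
  per_emitter <- lapply(seq_len(ne), render1)
  zero <- matrix(0, scene$height, scene$width)
  frames <- lapply(seq_len(blink$n_frames), function(t) {
    f <- zero
    for (e in which(on_states[, t])) f <- f + per_emitter[[e]]
    image_frame(f, pixel_size = scene$pixel_size)
  })
  list(stack = image_stack(frames), on_states = on_states)
}

#' Camera model and photon-to-counts conversion
#'
#' `camera_model()` holds an sCMOS-style calibration: per-pixel offset `O`
#' (counts), gain `G` (counts per electron), readout noise `N_r` (electrons
#' RMS) and quantum efficiency `QE`. `apply_camera()` converts an ideal
#' photon-rate frame to camera counts:
#' `counts = G * (Poisson(QE * photons) + Normal(0, N_r)) + O`,
#' i.e. shot noise on detected photoelectrons, then readout noise, then gain
#' and offset. Inverting with [electrons()] recovers photoelectrons in
#' expectation.
#'
#' @param offset offset map in counts (scalar or matrix).
#' @param gain gain map in counts per electron (scalar or matrix, > 0).
#' @param readout_noise readout noise in electrons RMS, >= 0.
#' @param qe quantum efficiency in `(0, 1]`.
#' @return `camera_model()` returns a `camera_model` object; `apply_camera()`
#'   an [image_frame()] in camera counts.
#' @examples
#' cam <- camera_model(offset = 100, gain = 2, readout_noise = 1, qe = 0.72)
#' fr <- image_frame(matrix(50, 8, 8))
#' counts <- apply_camera(fr, cam, rng_seed = 7)
#' @export
camera_model <- function(offset = 100, gain = 2, readout_noise = 1, qe = 0.72) {
  if (any(gain <= 0)) stop("`gain` must be > 0 everywhere", call. = FALSE)
  if (qe <= 0 || qe > 1) stop("`qe` must be in (0, 1]", call. = FALSE)
  if (readout_noise < 0) stop("`readout_noise` must be >= 0", call. = FALSE)
  structure(list(offset = offset, gain = gain,
                 readout_noise = readout_noise, qe = qe),
            class = "camera_model")
}

#' @rdname camera_model
#' @param frame_photons non-negative photon-rate frame.
#' @param cam a `camera_model`.
#' @param rng_seed integer seed making the draw reproducible.
#' @export
apply_camera <- function(frame_photons, cam, rng_seed = 1L) {
  if (!inherits(cam, "camera_model")) stop("`cam` must be a camera_model")
  ph <- as_pixel_matrix(as_image_frame(frame_photons))
  if (any(ph < 0))
    stop("photon frame must be non-negative", call. = FALSE)
  n <- length(ph)
  counts <- with_seed(rng_seed, {
    pe <- rpois(n, cam$qe * ph)
    if (cam$readout_noise > 0) pe <- pe + rnorm(n, 0, cam$readout_noise)
    cam$gain * pe + cam$offset
  })
  out <- matrix(counts, nrow(ph), ncol(ph))
  image_frame(out, pixel_size = pixel_size(frame_photons))
}

#' Write a simulated scene to disk with its ground truth
#'
#' Writes the rendered frame (or stack) as 32-bit float TIFF plus a JSON
#' sidecar holding the ground truth: emitter coordinates in nm, the ON/OFF
#' matrix for blinking stacks, the seed and any camera constants.
#'
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param frames an [image_frame()] or [image_stack()].
#' @param scene the [emitter_scene()] that generated `frames`.
#' @param extra named list merged into the sidecar (e.g. seed, camera).
#' @return Invisibly, the sidecar path.
#' @export
write_scene <- function(path, frames, scene, extra = list()) {
  write_tiff(frames, path)
  gt <- c(list(
    emitters_nm = data.frame(
      x = scene$emitters$x * scene$pixel_size,
      y = scene$emitters$y * scene$pixel_size,
      amplitude = scene$emitters$amplitude),
    field_px = c(scene$width, scene$height),
    pixel_size_nm = scene$pixel_size), extra)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(gt, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
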