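#' Image frame: a 2D intensity raster with pixel-size metadata
#'
#' The basic unit all operations consume and produce. A frame is a numeric
#' matrix of finite intensities with an optional physical pixel size
#' (nm per pixel) carried as an attribute. Pixel centers sit at integer
#' coordinates, 0-based, with x running along columns and y along rows.
#'
#' @param pixels numeric matrix of intensities (finite, at least 1 x 1).
#' @param pixel_size physical pixel size in nm/px, or `NA` if unknown.
#' @return An `image_frame` object (a matrix with class and `pixel_size`
#'   attributes).
#' @examples
#' f <- image_frame(matrix(0, 5, 5), pixel_size = 100)
#' pixel_size(f)
#' @export
image_frame <- function(pixels, pixel_size = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("frame dimensions must be at least 1 x 1", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("frame contains non-finite values", call. = FALSE)
  structure(pixels, pixel_size = as.numeric(pixel_size),
            class = c("image_frame", class(pixels)))
}

#' @rdname image_frame
#' @param x object to coerce or query.
#' @export
as_image_frame <- function(x, pixel_size = NA_real_) {
  if (inherits(x, "image_frame")) return(x)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  image_frame(as.matrix(x), pixel_size)
}

#' @rdname image_frame
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) NA_real_ else ps
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, pixel size %s nm/px, range [%g, %g]\n",
              nrow(x), ncol(x),
              if (is.na(pixel_size(x))) "?" else format(pixel_size(x)),
              min(x), max(x)))
  invisible(x)
}

# strip class/attrs down to a plain matrix for arithmetic-heavy code paths
as_pixel_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "pixel_size") <- NULL
  m
}

#' Image stack: an ordered sequence of co-registered frames
#'
#' A time-ordered list of frames of identical shape, the input unit of
#' temporal analysis ([t_mssr()], [apply_ptf()]).
#'
#' @param frames list of matrices / `image_frame`s, all the same shape.
#' @param frame_interval optional frame interval in seconds.
#' @return An `image_stack` object.
#' @examples
#' s <- image_stack(list(matrix(1, 4, 4), matrix(2, 4, 4)))
#' length(s)
#' @export
image_stack <- function(frames, frame_interval = NA_real_) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list", call. = FALSE)
  frames <- lapply(frames, as_image_frame)
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same))
    stop("all frames in a stack must share the same dimensions", call. = FALSE)
  structure(frames, frame_interval = as.numeric(frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px\n", length(x), d[1], d[2]))
  invisible(x)
}

# stack -> (n_pixels x n_frames) matrix; used by the pixel-wise temporal code
stack_as_matrix <- function(stack) {
  np <- length(stack[[1]])
  matrix(vapply(stack, function(f) as.numeric(as_pixel_matrix(f)),
                numeric(np)),
         nrow = np, ncol = length(stack))
}

#' Extract the intensity profile through the brightest pixel
#'
#' Returns the row (profile along x) or column (along y) passing through the
#' global intensity maximum, together with physical coordinates when the frame
#' carries a pixel size. Ties in the maximum resolve to the first occurrence
#' in column-major order.
#'
#' @param frame an `image_frame` or matrix.
#' @param axis `"x"` (row through the peak) or `"y"` (column through the peak).
#' @return A data.frame with columns `coord` (px or nm) and `intensity`.
#' @export
peak_profile <- function(frame, axis = c("x", "y")) {
  axis <- match.arg(axis)
  m <- as_pixel_matrix(as_image_frame(frame))
  idx <- arrayInd(which.max(m), dim(m))
  v <- if (axis == "x") m[idx[1], ] else m[, idx[2]]
  ps <- pixel_size(frame)
  step <- if (is.na(ps)) 1 else ps
  n <- length(v)
  data.frame(coord = (seq_len(n) - (n + 1) / 2) * step, intensity = v)
}
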