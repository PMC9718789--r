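#' Pixel-wise temporal functions (PTFs)
#'
#' Collapses an image stack to a single frame by applying a statistic to each
#' pixel's time series `F_t`:
#' \describe{
#'   \item{MEAN}{time average.}
#'   \item{VAR}{population variance, the 2nd central moment.}
#'   \item{CV}{coefficient of variation `sd(F) / mean(F)`; 0 where the mean
#'     is 0 so outputs stay renderable.}
#'   \item{TPM}{temporal product mean: the mean of consecutive-frame products
#'     `mean(F_t * F_{t+1})` — order-dependent, unlike the other PTFs.}
#'   \item{SOFI2, SOFI3, SOFI4}{auto-cumulants of the mean-subtracted series
#'     at zero time lag: `k2 = <dF^2>`, `k3 = <dF^3>`,
#'     `k4 = <dF^4> - 3 <dF^2>^2`.}
#' }
#' Cumulants of order 3 and up vanish for Gaussian fluctuations, which is why
#' SOFI-type statistics suppress uncorrelated detector noise while keeping
#' correlated blinking signal.
#'
#' @param stack an [image_stack()] (or list of frames).
#' @param ptf one of `"MEAN"`, `"VAR"`, `"TPM"`, `"CV"`, `"SOFI2"`,
#'   `"SOFI3"`, `"SOFI4"`.
#' @return An [image_frame()].
#' @examples
#' st <- image_stack(list(matrix(0, 2, 2), matrix(2, 2, 2),
#'                        matrix(0, 2, 2), matrix(2, 2, 2)))
#' apply_ptf(st, "SOFI2")[1, 1]  # 1
#' @export
apply_ptf <- function(stack, ptf = c("MEAN", "VAR", "TPM", "CV",
                                     "SOFI2", "SOFI3", "SOFI4")) {
  ptf <- match.arg(ptf)
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  nt <- length(stack)
  if (ptf != "MEAN" && nt < 2L)
    stop(sprintf("PTF %s needs at least 2 frames", ptf), call. = FALSE)
  X <- stack_as_matrix(stack)            # pixels x frames
  m1 <- rowMeans(X)
  out <- switch(ptf,
    MEAN = m1,
    TPM = rowMeans(X[, -nt, drop = FALSE] * X[, -1L, drop = FALSE]),
    {
      d <- X - m1
      k2 <- rowMeans(d * d)
      switch(ptf,
        VAR = k2,
        CV = ifelse(m1 == 0, 0, sqrt(k2) / m1),
        SOFI2 = k2,
        SOFI3 = rowMeans(d * d * d),
        SOFI4 = rowMeans(d * d * d * d) - 3 * k2 * k2)
    })
  d1 <- dim(stack[[1]])
  image_frame(matrix(out, d1[1], d1[2]), pixel_size = pixel_size(stack[[1]]))
}

#' Temporal MSSR
#'
#' Applies single-frame MSSR with shared parameters to every frame of a
#' stack, then collapses the processed stack with a pixel-wise temporal
#' function. Fourier interpolation is the default magnification for temporal
#' runs (bicubic remains selectable by setting `interpolation` explicitly in
#' `params`). With `ptf = "MEAN"` on a single-frame stack the result equals
#' the single-frame analysis exactly.
#'
#' @param stack an [image_stack()].
#' @param params an [mssr_params()]; if `interpolation` was left at its
#'   default, temporal analysis switches it to `"fourier"`.
#' @param ptf pixel-wise temporal function, see [apply_ptf()].
#' @return An [image_frame()] of `amp` times the input frame dimensions.
#' @export
t_mssr <- function(stack, params, ptf = "MEAN") {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  if (!inherits(params, "mssr_params"))
    stop("`params` must be an mssr_params object", call. = FALSE)
  if (!isTRUE(params$interp_given) && params$interpolation == "bicubic")
    params$interpolation <- "fourier"
  processed <- lapply(stack, sf_mssr, params = params)
  apply_ptf(image_stack(processed), ptf)
}
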