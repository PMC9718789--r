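# interpolation, mean-shift computation, algebraic transforms and sf-MSSR

test_that("interpolation contract: identity at amp 1, constants preserved", {
  fr <- image_frame(matrix(runif(64), 8, 8))
  expect_frames_equal(interpolate_frame(fr, 1, "bicubic"), fr)
  expect_frames_equal(interpolate_frame(fr, 1, "fourier"), fr)
  for (mode in c("bicubic", "fourier")) {
    up <- interpolate_frame(image_frame(matrix(3.7, 6, 9)), 4, mode)
    expect_identical(dim(unclass(up)), c(24L, 36L))
    expect_equal(range(unclass(up)), c(3.7, 3.7), tolerance = 1e-12)
  }
  expect_error(interpolate_frame(fr, 0), "positive integer")
})

test_that("bicubic upsampling of a sampled Gaussian tracks the analytic form", {
  sigma <- 6
  sc <- single_emitter_scene(24)
  coarse <- render_gaussian(sc, gaussian_psf(sigma))
  up <- unclass(interpolate_frame(coarse, 4, "bicubic"))
  # analytic resampling on the magnified grid (input pixel k at coord k/amp)
  n <- nrow(up)
  coords <- (0:(n - 1)) / 4
  fine <- outer((coords - 24)^2, (coords - 24)^2, `+`)
  fine <- exp(-fine / (2 * sigma^2))
  interior <- 5:(n - 8)   # clamped frame edge excluded
  expect_lt(max(abs(up[interior, interior] - fine[interior, interior])), 0.01)
})

test_that("fourier interpolation is exact on band-limited content", {
  n <- 16
  x <- 0:(n - 1)
  img <- outer(sin(2 * pi * 2 * x / n), cos(2 * pi * 3 * x / n)) + 2
  up <- unclass(interpolate_frame(image_frame(img), 3, "fourier"))
  X <- (0:(3 * n - 1)) / 3
  expected <- outer(sin(2 * pi * 2 * X / n), cos(2 * pi * 3 * X / n)) + 2
  expect_equal(up, expected, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("mean shift of a constant image is zero everywhere", {
  ms <- mean_shift(image_frame(matrix(5, 12, 12)), h_s = 3)
  expect_equal(max(abs(ms)), 0)
})

test_that("1D toy mean shift matches hand summation with range weights off", {
  # radius-1 window on [1 2 4 2 1]: center value (2+4+2)/3 - 4 = -4/3
  ms <- mean_shift(matrix(c(1, 2, 4, 2, 1), nrow = 1), h_s = 1, h_r = Inf)
  expect_equal(ms[1, 3], (2 + 4 + 2) / 3 - 4)
})

test_that("the mean-shift minimum sits at the intensity maximum of a Gaussian", {
  fr <- render_gaussian(single_emitter_scene(30), gaussian_psf(6))
  ms <- mean_shift(fr, h_s = 7)
  expect_identical(which.min(ms), which.max(unclass(fr)))
  expect_lt(min(ms), 0)
})

test_that("vectorized mean shift equals the brute-force double loop", {
  set.seed(101)
  for (rep in 1:4) {
    img <- matrix(runif(256), 16, 16)
    hr <- diff(range(img))
    for (bnd in c("mirror", "constant")) {
      fast <- mean_shift(image_frame(img), h_s = 3, h_r = hr, boundary = bnd)
      slow <- ms_brute(img, hs = 3, hr = hr, boundary = bnd)
      expect_lt(max(abs(unclass(fast) - slow)), 1e-10)
    }
  }
})

test_that("mean shift validates its bandwidths", {
  fr <- image_frame(matrix(runif(25), 5, 5))
  expect_error(mean_shift(fr, h_s = 0), "h_s")
  expect_error(mean_shift(fr, h_s = 99), "larger than the image")
  expect_error(mean_shift(fr, h_s = 2, h_r = -1), "h_r")
})

test_that("transform stages: zero field maps to zero frame with warning", {
  ref <- image_frame(matrix(runif(36), 6, 6))
  expect_warning(out <- apply_transforms(matrix(0, 6, 6), ref), "degenerate")
  expect_equal(max(abs(unclass(out))), 0)
  expect_error(apply_transforms(matrix(0, 3, 3), ref), "same shape")
})

test_that("transform output is non-negative and preserves the peak position", {
  fr <- render_gaussian(single_emitter_scene(30), gaussian_psf(6))
  ms <- mean_shift(fr, h_s = 7)
  out <- apply_transforms(ms, fr)
  expect_gte(min(unclass(out)), 0)
  expect_identical(which.max(unclass(out)), which.max(unclass(fr)))
  # clipped stage-2 zeros stay zero after weighting
  clipped <- pmax(-unclass(ms) * 1, 0)
  expect_true(all(unclass(out)[clipped == 0] == 0))
})

test_that("order-0 output of a single emitter is strictly narrower", {
  fr <- render_gaussian(single_emitter_scene(40), gaussian_psf(10))
  p <- mssr_params(amp = 1, psf_fwhm = 2 * sqrt(2 * log(2)) * 10, order = 0,
                   interpolation = "none")
  out <- sf_mssr0(fr, p)
  ratio <- measure_fwhm(peak_profile(out)) / measure_fwhm(peak_profile(fr))
  expect_lt(ratio, 0.65)
  expect_identical(which.max(unclass(out)), which.max(unclass(fr)))
})

test_that("a constant frame is annihilated at any order", {
  p <- mssr_params(amp = 1, psf_fwhm = 4, order = 2, interpolation = "none")
  w <- capture_warnings(out <- sf_mssr(image_frame(matrix(2, 16, 16)), p))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(max(abs(unclass(out))), 0)
})

test_that("processing reduces the dip of a near-limit emitter pair", {
  sc <- two_emitter_scene(2.5, sigma = 8)
  fr <- render_gaussian(sc, gaussian_psf(8))
  p <- mssr_params(amp = 1, psf_fwhm = 2 * sqrt(2 * log(2)) * 8, order = 0,
                   interpolation = "none")
  expect_lt(dip(sf_mssr0(fr, p)), dip(fr))
})

test_that("order 0 of the iterated form equals the order-0 transform", {
  fr <- render_gaussian(single_emitter_scene(25), gaussian_psf(5))
  p <- mssr_params(amp = 1, psf_fwhm = 11.8, order = 0, interpolation = "none")
  expect_frames_equal(sf_mssr(fr, p), sf_mssr0(fr, p))
})

test_that("single-emitter FWHM decreases monotonically with order", {
  fr <- render_gaussian(single_emitter_scene(40), gaussian_psf(10))
  p <- mssr_params(amp = 1, psf_fwhm = 23.55, order = 3, interpolation = "none")
  series <- sf_mssr_series(fr, p)
  widths <- c(measure_fwhm(peak_profile(fr)),
              vapply(series, function(f) measure_fwhm(peak_profile(f)),
                     numeric(1)))
  expect_true(all(diff(widths) < 0))
})

test_that("sf_mssr is equivariant to intensity rescaling", {
  fr <- render_gaussian(single_emitter_scene(30), gaussian_psf(6))
  p <- mssr_params(amp = 1, psf_fwhm = 14.1, order = 2, interpolation = "none")
  out1 <- unclass(sf_mssr(fr, p))
  out5 <- unclass(sf_mssr(image_frame(unclass(fr) * 5), p))
  expect_equal(out5, 5 * out1, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("well-separated peaks keep their positions through processing", {
  sigma <- 5
  sc <- two_emitter_scene(6, sigma = sigma, max_separation_in_sigma = 6)
  fr <- render_gaussian(sc, gaussian_psf(sigma))
  p <- mssr_params(amp = 1, psf_fwhm = 2 * sqrt(2 * log(2)) * sigma,
                   order = 1, interpolation = "none")
  out <- unclass(sf_mssr(fr, p))
  m <- unclass(fr)
  for (e in seq_len(2)) {
    col_true <- round(sc$emitters$x[e]) + 1
    row_true <- round(sc$emitters$y[e]) + 1
    # local maximum of the output near the true position
    win <- out[row_true + (-3:3), col_true + (-3:3)]
    idx <- arrayInd(which.max(win), dim(win))
    expect_lte(max(abs(idx - 4)), 1)
  }
})

test_that("magnified runs scale the kernel and shrink the pixel size", {
  fr <- render_gaussian(single_emitter_scene(16, pixel_size = 20),
                        gaussian_psf(4))
  p <- mssr_params(amp = 2, psf_fwhm = 9.4, order = 0)
  out <- sf_mssr0(fr, p)
  expect_identical(dim(unclass(out)), c(66L, 66L))
  expect_equal(pixel_size(out), 10)
})

test_that("mesh minimization is off by default and only smooths when asked", {
  fr <- render_gaussian(single_emitter_scene(16), gaussian_psf(4))
  p0 <- mssr_params(amp = 2, psf_fwhm = 9.4, order = 0)
  p1 <- mssr_params(amp = 2, psf_fwhm = 9.4, order = 0,
                    mesh_minimization = TRUE)
  out0 <- sf_mssr0(fr, p0)
  out1 <- sf_mssr0(fr, p1)
  expect_false(isTRUE(all.equal(unclass(out0), unclass(out1))))
  # amp = 1: the flag must not alter results
  p2 <- mssr_params(amp = 1, psf_fwhm = 9.4, order = 0,
                    interpolation = "none", mesh_minimization = TRUE)
  p3 <- mssr_params(amp = 1, psf_fwhm = 9.4, order = 0, interpolation = "none")
  expect_frames_equal(sf_mssr0(fr, p2), sf_mssr0(fr, p3))
})
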