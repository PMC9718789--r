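# emitter rendering, blinking stacks and the camera noise model

test_that("Gaussian rendering samples the PSF formula exactly", {
  sc <- single_emitter_scene(40)            # 81 x 81, sigma = 10 grid
  fr <- render_gaussian(sc, gaussian_psf(10))
  m <- unclass(fr)
  expect_identical(dim(m), c(81L, 81L))
  expect_equal(m[41, 41], 1)                        # peak at emitter pixel
  expect_equal(m[41, 51], exp(-0.5))                # one sigma off-center
  pr <- peak_profile(fr)
  expect_equal(measure_fwhm(pr), 2 * sqrt(2 * log(2)) * 10, tolerance = 1e-3)
  # matches the direct double-loop evaluation
  expect_equal(m, gauss_field(81, 81, cbind(40, 40), 10), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Gaussian rendering errors on invalid input", {
  expect_error(emitter_scene(data.frame(x = 1, y = 1, amplitude = 1)[0, ],
                             width = 9, height = 9), "empty scene")
  expect_error(gaussian_psf(0), "sigma")
  expect_error(gaussian_psf(-2), "sigma")
  expect_error(emitter_scene(data.frame(x = 99, y = 1, amplitude = 1),
                             width = 9, height = 9), "inside the field")
})

test_that("Bessel rendering matches the Airy pattern", {
  expect_error(bessel_psf(lambda_em = -5, na = 1.4), "lambda_em")
  expect_error(bessel_psf(lambda_em = 525, na = 0), "na")
  spec <- bessel_psf(lambda_em = 525, na = 1.4)
  sc <- single_emitter_scene(192, pixel_size = 2)    # +-384 nm at 2 nm/px
  fr <- render_bessel(sc, spec)
  m <- unclass(fr)
  expect_equal(m[193, 193], 1)                       # I0 at q = 0
  # intensity vanishes at the first root of J1 (bracketing/bisection oracle)
  v_root <- j1_first_root()
  q_root <- v_root / ((2 * pi / 525) * 1.4)          # nm
  prof <- peak_profile(fr)
  at_root <- approx(prof$coord, prof$intensity, xout = q_root)$y
  expect_lt(at_root, 1e-4)
  # first dark ring radius matches the Rayleigh distance 0.61 lambda / NA
  expect_equal(q_root, 0.61 * 525 / 1.4, tolerance = 0.002)
})

test_that("Bessel PSF width matches its Gaussian-core equivalent", {
  sc <- single_emitter_scene(192, pixel_size = 2)
  fr <- render_bessel(sc, bessel_psf(lambda_em = 525, na = 1.4))
  prof <- peak_profile(fr)
  expect_equal(measure_fwhm(prof), 192, tolerance = 0.01)
  expect_equal(fit_gaussian_sigma(prof), 79, tolerance = 2 / 79)
})

test_that("two-emitter scenes place emitters symmetrically", {
  sc0 <- two_emitter_scene(0, sigma = 10)
  expect_equal(sc0$emitters$x[1], sc0$emitters$x[2])
  sc <- two_emitter_scene(2, sigma = 10)
  expect_equal(diff(sc$emitters$x), 20)
  expect_equal(sc$emitters$y[1], sc$emitters$y[2])
  expect_error(two_emitter_scene(-1, sigma = 10), ">= 0")
})

test_that("rendering is linear and translation-equivariant", {
  psf <- gaussian_psf(4)
  base <- data.frame(x = c(10, 22), y = c(15, 18), amplitude = c(1, 2))
  scA <- emitter_scene(base[1, ], 41, 41)
  scB <- emitter_scene(base[2, ], 41, 41)
  scAB <- emitter_scene(base, 41, 41)
  expect_frames_equal(render_gaussian(scAB, psf),
                      unclass(render_gaussian(scA, psf)) +
                        unclass(render_gaussian(scB, psf)))
  shifted <- base
  shifted$x <- shifted$x + 3
  shifted$y <- shifted$y + 5
  mS <- unclass(render_gaussian(emitter_scene(shifted, 41, 41), psf))
  m0 <- unclass(render_gaussian(scAB, psf))
  inner <- m0[1:30, 1:30]
  expect_equal(mS[6:35, 4:33], inner, tolerance = 1e-12)
})

test_that("a rendered Gaussian emitter is recovered by fitting", {
  sc <- single_emitter_scene(60)
  fr <- render_gaussian(sc, gaussian_psf(7.5))
  expect_equal(fit_gaussian_sigma(peak_profile(fr)), 7.5, tolerance = 1e-3)
})

test_that("blinking stacks honor degenerate on-probabilities", {
  sc <- two_emitter_scene(3, sigma = 4)
  psf <- gaussian_psf(4)
  full <- render_gaussian(sc, psf)
  on <- blinking_stack(sc, psf, blinking_spec(5, 1, seed = 3))
  for (f in on$stack) expect_frames_equal(f, full)
  off <- blinking_stack(sc, psf, blinking_spec(4, 0, seed = 3))
  for (f in off$stack) expect_equal(max(unclass(f)), 0)
  expect_error(blinking_spec(0, 0.5), "empty")
})

test_that("mean ON fraction matches the Bernoulli rate", {
  sc <- two_emitter_scene(3, sigma = 4)
  b <- blinking_stack(sc, gaussian_psf(4), blinking_spec(300, 0.3, seed = 11))
  frac <- mean(b$on_states)
  se <- sqrt(0.3 * 0.7 / length(b$on_states))
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("blinking stacks are bit-reproducible for a fixed seed", {
  sc <- two_emitter_scene(2, sigma = 4)
  psf <- gaussian_psf(4)
  b1 <- blinking_stack(sc, psf, blinking_spec(20, 0.4, seed = 42))
  b2 <- blinking_stack(sc, psf, blinking_spec(20, 0.4, seed = 42))
  expect_identical(b1$on_states, b2$on_states)
  for (t in seq_along(b1$stack)) expect_frames_equal(b1$stack[[t]], b2$stack[[t]])
  b3 <- blinking_stack(sc, psf, blinking_spec(20, 0.4, seed = 43))
  expect_false(identical(b1$on_states, b3$on_states))
})

test_that("camera model: zero photons and zero readout give the offset map", {
  cam <- camera_model(offset = 100, gain = 2, readout_noise = 0, qe = 0.72)
  fr <- image_frame(matrix(0, 6, 6))
  out <- apply_camera(fr, cam, rng_seed = 5)
  expect_equal(unclass(out), matrix(100, 6, 6), ignore_attr = TRUE)
  expect_error(apply_camera(image_frame(matrix(-1, 2, 2)) * 1, cam),
               "non-negative")
})

test_that("count inversion recovers detected photoelectrons in expectation", {
  cam <- camera_model(offset = 100, gain = 2, readout_noise = 1, qe = 0.72)
  photons <- 50
  fr <- image_frame(matrix(photons, 20, 20))
  draws <- vapply(1:25, function(s)
    mean(electrons(unclass(apply_camera(fr, cam, rng_seed = s)),
                   cam$offset, cam$gain)),
    numeric(1))
  n_total <- 25 * 400
  se <- sqrt(0.72 * photons + 1) / sqrt(n_total)
  expect_lt(abs(mean(draws) - 0.72 * photons), 4 * se)
})

test_that("camera draws are reproducible per seed", {
  cam <- camera_model()
  fr <- image_frame(matrix(10, 5, 5))
  expect_identical(unclass(apply_camera(fr, cam, 9)),
                   unclass(apply_camera(fr, cam, 9)))
  expect_false(identical(unclass(apply_camera(fr, cam, 9)),
                         unclass(apply_camera(fr, cam, 10))))
})

test_that("scene sidecar records ground truth in nm", {
  sc <- two_emitter_scene(2, sigma = 5, pixel_size = 100)
  fr <- render_gaussian(sc, gaussian_psf(5))
  path <- tempfile(fileext = ".tif")
  sidecar <- write_scene(path, fr, sc, extra = list(seed = 7))
  gt <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  expect_equal(gt$pixel_size_nm, 100)
  expect_equal(gt$emitters_nm$x, sc$emitters$x * 100)
  expect_equal(gt$seed, 7)
})
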