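# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain double loops and direct formula
# evaluation.

# brute-force mean-shift field: explicit loop over pixels and neighborhood
# offsets, mirror or zero padding, uniform spatial weights over the disk of
# radius hs (center included), Gaussian range weights
ms_brute <- function(img, hs, hr, boundary = "mirror") {
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(k, n) {
    while (k < 1 || k > n) {
      if (k < 1) k <- 2 - k
      if (k > n) k <- 2 * n - k
    }
    k
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    num <- 0; den <- 0; c0 <- img[i, j]
    for (di in -hs:hs) for (dj in -hs:hs) {
      if (di * di + dj * dj > hs * hs) next
      ii <- i + di; jj <- j + dj
      if (boundary == "mirror") {
        v <- img[refl(ii, nr), refl(jj, nc)]
      } else {
        v <- if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) img[ii, jj] else 0
      }
      w <- exp(-(v - c0)^2 / (2 * hr^2))
      num <- num + w * v
      den <- den + w
    }
    out[i, j] <- num / den - c0
  }
  out
}

# direct evaluation of a sum of 2D Gaussians on a pixel grid
# (0-based pixel coordinates, like the scene convention)
gauss_field <- function(width, height, centers, sigma, amplitude = 1) {
  out <- matrix(0, height, width)
  for (i in seq_len(height)) for (j in seq_len(width)) {
    x <- j - 1; y <- i - 1
    for (k in seq_len(nrow(centers)))
      out[i, j] <- out[i, j] + amplitude *
        exp(-((x - centers[k, 1])^2 + (y - centers[k, 2])^2) / (2 * sigma^2))
  }
  out
}

# first positive root of the order-1 Bessel function by bisection
j1_first_root <- function(tol = 1e-10) {
  lo <- 3; hi <- 4.5   # J1(3) > 0, J1(4.5) < 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (besselJ(mid, 1) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

expect_frames_equal <- function(a, b, tol = 1e-12) {
  expect_equal(unclass(a) + 0, unclass(b) + 0, tolerance = tol,
               ignore_attr = TRUE)
}
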