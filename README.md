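# mssr

Mean-shift super-resolution (MSSR) analysis for fluorescence microscopy in R.

Optical diffraction blurs every point emitter into a point-spread function
(PSF) a few hundred nanometers wide, so fluorophores closer than roughly the
Rayleigh distance 0.61 λ/NA merge into one blob. MSSR is a purely
computational route to sharper images: it needs a *single* diffraction-limited
frame (no special optics, no blinking statistics), and optionally improves
further when a time stack is available. This package implements the method
for image analysts and microscopists, together with the simulation and
evaluation machinery needed to characterize its resolution on synthetic
ground truth.

## The method in brief

For an image `I`, the mean-shift field over a spatial–range neighborhood
(disk of radius `h_s`, Gaussian range weights of bandwidth `h_r`) is

```
MS(x) = Σ_y w_s(‖y−x‖) w_r(I(y)−I(x)) I(y) / Σ_y w_s w_r − I(x)
```

The field is most negative exactly at emitter peaks. The order-0 transform
negates it, clips the negative "valley" artifact to zero, min–max
normalizes, and multiplies by `I` — yielding an image whose emitters are
markedly narrower but sit at the same positions (`sf_mssr0()`). Higher
orders iterate by subtracting the residual between consecutive orders
(`sf_mssr()`); for stacks, a pixel-wise temporal function — Mean, Var, CV,
TPM or SOFI-style auto-cumulants — collapses per-frame results into one
super-resolved image (`t_mssr()`). The only physical parameter is the PSF
FWHM in pixels; `amp` sets digital magnification by bicubic or Fourier
interpolation.

## Worked example

Render a 525 nm / NA 1.4 diffraction-limited emitter (Bessel PSF, 2 nm
pixels) and sharpen it through orders 0–3:

```r
library(mssr)

scene <- single_emitter_scene(192, pixel_size = 2)       # ±384 nm field
frame <- render_bessel(scene, bessel_psf(lambda_em = 525, na = 1.4))

params <- mssr_params(amp = 1, psf_fwhm = 99,            # 198 nm in 2 nm px
                      order = 3, interpolation = "none")
series <- sf_mssr_series(frame, params)                  # orders 0..3

for (fr in c(list(frame), series)) {
  prof <- peak_profile(fr)
  cat(sprintf("FWHM %6.2f nm   sigma %5.2f nm\n",
              measure_fwhm(prof), fit_gaussian_sigma(prof)))
}
#> FWHM 192.94 nm   sigma 78.90 nm      (diffraction-limited input)
#> FWHM 116.03 nm   sigma 48.33 nm      (order 0)
#> FWHM  76.32 nm   sigma 30.61 nm      (order 1)
#> FWHM  51.94 nm   sigma 20.71 nm      (order 2)
#> FWHM  35.51 nm   sigma 14.15 nm      (order 3)
```

Each order roughly halves the width every two iterations: a 193 nm-wide
emitter ends up 36 nm wide after three iterations, while its peak stays put.

Two-point resolution is characterized with dip curves — the intensity at the
midpoint between two emitters relative to the distribution maximum, scanned
over the separation in units of the emitter sigma:

```r
scan <- seq(0, 4, by = 0.1)
dl <- dip_curve("DL", scan, sigma = 10)   # unprocessed pair
o0 <- dip_curve(0,    scan, sigma = 10)   # after order-0 processing

resolution_limit(dl, "sparrow")                      # 2.0  (sigma units)
resolution_limit(dl, "rayleigh", dip_value = 0.74)   # 2.789
resolution_limit(o0, "rayleigh", dip_value = 0.74)   # 2.096
```

The order-0 transform moves the 0.74-dip Rayleigh crossing from 2.79 σ to
2.10 σ — a ~25 % resolution improvement from a single frame. For an emitter
with σ = 79 nm that is a resolution of about 166 nm.

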