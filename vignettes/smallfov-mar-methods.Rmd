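---
title: "Metal artifact reduction for small-FOV fan-beam CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metal artifact reduction for small-FOV fan-beam CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(smallfovmar)
```

## The problem

Sinogram-inpainting metal artifact reduction (MAR) treats the sinogram
samples whose rays cross metal — the *metal trace* — as missing data and
fills them in, either by linear interpolation along the detector (LMAR) or
after flattening the sinogram with a prior image (NMAR).  Both methods
assume the metal can be located in the reconstruction so its trace can be
found by forward projection, and that the samples neighbouring the trace
are trustworthy interpolation anchors.

When the scan field of view (FOV) is smaller than the object — dental CT,
biopsy needles, any truncated acquisition — both assumptions fail for
metal outside the FOV: it is invisible in the reconstruction, so its trace
cannot be identified, and its trace corrupts the anchors used to inpaint
the traces of the visible metals.  The remedy implemented here is to stop
inpainting the measured sinogram altogether: first reconstruct a
truncation-corrected small-FOV image, then forward project it into a
*synthesized* sinogram that is consistent with the small FOV and free of
out-of-FOV contributions, and inpaint that instead.

## Pipeline

Both pipelines start from the measured log-projection sinogram
`p = -log(y / I0)`.

1. **Truncation correction.**  Each truncated sinogram row is extended by
   `N_s` samples per side obtained by reflecting the innermost `N_ext`
   measured samples about the detector edge and tapering them with a
   quarter-cosine so the extension decays to zero
   (`truncation_weight()`, `extend_sinogram()`).  `N_ext` defaults to 300
   detector pixels for the conventional geometry and 150 for the dental
   one, scaled with the detector size.  The taper length is `N_ext`
   samples; we default `N_s = N_ext` so the extension reaches exactly
   zero, and a side is considered truncated when its edge sample exceeds
   1% of the row maximum (this stops air scans from being extended).
   Filtered backprojection of the widened sinogram, masked to the scan
   FOV, gives the small-FOV image (`truncation_corrected_recon()`).
2. **Sinogram synthesis** (proposed pipeline only).  The small-FOV image
   is forward projected with a five-fold finer detector sampling and
   block-averaged back to the native grid (`forward_project()`,
   `rebin_detector()`); the oversampling suppresses discretization error
   in the synthesized sinogram.
3. **Inpainting MAR.**  Metal is segmented from the small-FOV image by
   simple thresholding (default 2000 HU), its trace found by forward
   projection of the binary mask (dilated by one detector bin), and the
   target sinogram — synthesized for the proposed pipeline, measured for
   the baseline — is inpainted.  LMAR interpolates linearly along the
   detector within each trace run.  NMAR builds a prior image from the
   LMAR reconstruction (bone kept, soft tissue set to the mean of
   artifact-free soft tissue, air zeroed), forward projects it, flattens
   the sinogram by the prior sinogram, inpaints, and denormalizes.  The
   segmented metal pixels are pasted back into the final image.

The baseline ("previous") pipeline reconstructs the inpainted *measured*
sinogram, with the same truncation extension applied before the final
backprojection so that residual differences between the two pipelines
reflect metal artifact handling rather than truncation bias.

## System model

The projector is ray-driven (Joseph): for each source-detector ray the
image is sampled at each pixel-plane crossing along the dominant axis with
linear interpolation transverse to it.  Its exact algebraic transpose is
available (`backproject_adjoint()`) and agrees with the projector to
machine precision in the inner-product test, which matters for any
gradient-based extension.  Reconstruction is standard flat-detector
fan-beam FBP: detector coordinates rescaled to the iso-centre line, cosine
pre-weighting, discrete Ram–Lak ramp filtering (frequency domain,
zero-padded to at least four native detector lengths so that a symmetric
detector extension never changes the filter), optional Hann apodization
(the default, as in most practical FBP implementations), and inverse-square
distance-weighted backprojection with the half-weight accounting for the
two-fold redundancy of a full rotation.  720 views are spread uniformly
over [0, 2π).

Two bundled geometry presets cover the target systems:
`conventional` (source–iso 700 mm, detector–iso 500 mm, 1024 cells of
0.388 mm, 512 × 512 image of 358.4 mm) and `dental` (500 mm, 200 mm, 512
cells, 143.36 mm).  A point worth noting: for the conventional preset the
detector only covers a 228.7 mm circle at the iso-centre (the tangent
circle of the edge rays), which is *smaller* than the 358.4 mm image.
`scan_fov_radius()` returns this effective radius; it is what "small FOV"
means operationally throughout the package — truncation masking,
inside/outside metal placement and reference cropping all use it.

## Measurement model

Polychromatic intensities follow the spectrum-weighted Beer–Lambert sum
`I = I0 · Σ_E Ω(E) exp(−μ_w(E) d_w − μ_b(E) d_b − μ_m(E) d_m)` over twelve
10 keV bins from 10 to 120 keV, with per-material path lengths obtained by
forward projection of the material maps.  Counts are Poisson,
`y ~ Poisson(I + r)` with `I0 = 1e5` photons per cell and `r = 0` by
default, and the log transform floors counts at 0.5 so projections behind
dense metal stay finite (photon starvation).  Beam hardening emerges from
the energy sum rather than being modelled explicitly: log projections grow
sub-linearly in thickness and a uniform water disk reconstructs with the
classic cupping, both covered by tests, and both vanish in the
monochromatic (single-bin) limit where the whole chain collapses to a
single Beer–Lambert projection.

The shipped attenuation table holds NIST-derived mass attenuation for
water, cortical bone, gold (K edge at 80.7 keV) and iron/steel,
interpolated log-log onto the spectrum grid and scaled by densities 1.0,
1.92, 19.3 and 7.87 g/cm³.  The default tube spectrum is an analytic
120 kVp tungsten bremsstrahlung shape — Kramers' law hardened by 2.5 mm of
aluminium-equivalent filtration — since measured tube spectra are
typically proprietary; any two-column text table can be supplied instead
(`read_spectrum()`).  HU conversion uses
`HU = 1000 (μ − μ_w) / μ_w` with `μ_w` evaluated at a configurable 60 keV
effective energy.  Images are therefore only approximately HU-calibrated
under the polychromatic model; thresholds that matter (metal at 2000 HU,
bone at 660 HU) sit far from the soft-tissue band, so this approximation
is harmless for segmentation, but note that beam-hardened cortical bone
can legitimately exceed 2000 HU in dense phantoms — the reason the
metal/bone separation relies on metal reconstructing an order of
magnitude higher.

## Phantoms and the synthetic study

`make_disk_phantom()` emulates the bench experiment: a 250 mm water disk
carrying 32 cylinders of 5 mm diameter along its perimeter, a requested
number of them metal inside and outside the scan FOV, the rest
bone-density.  Two generator choices deserve justification:

* **Disk centre offset (default 40 mm).**  The cylinder ring has a 120 mm
  radius while the conventional-scan FOV radius is 114.3 mm; a concentric
  ring would place *every* cylinder outside the FOV and the prescribed
  "three metals inside, one-to-three outside" layout would be impossible.
  Offsetting the disk by 40 mm makes the ring straddle the FOV circle
  (about 13 slots inside), mirroring how such phantoms are positioned
  off-centre on the bench when the interesting region must stay inside
  a small FOV.
* **Cylinder metal (default steel).**  The bench experiment never states
  its insert metal.  Gold — used for the implant simulations — is so
  attenuating that a 5 mm cylinder extinguishes the beam completely
  (p ≈ 44); the resulting starvation streaks reconstruct at the same
  level as the metal itself and no threshold segmentation can work, for
  this package or any other.  Steel (iron, 7.87 g/cm³) gives p ≈ 9 behind
  a cylinder — severe but finite starvation, the regime the bench
  experiment plausibly operated in.  Gold remains the default for
  implant-style simulations via `attenuation_table(metal = "gold")`.

The reference image for quantitative evaluation crops the phantom to the
scan FOV (so no projection is truncated), removes all metal, and runs the
identical measurement and reconstruction chain.  Because the metal is
removed from the reference, the (dilated) true metal support is excluded
from the NMSE/SSIM statistics in `run_comparison()`: those pixels hold
the implant, not artifact.

What the generator does *not* emulate: realistic anatomy (no
anthropomorphic structures),
scatter, detector blur, bow-tie filtration, and the exact bench spectrum.
Passing the ordering tests therefore shows that the pipelines behave as
intended under a faithful polychromatic fan-beam simulation, not that
absolute NMSE/SSIM values transfer to any particular scanner.

## Metrics

`nmse()` implements `mean((f − f_ref)²) / (mean(f) · mean(f_ref))` over a
rectangular ROI — invariant under common rescaling and intended for
strictly positive attenuation images (an explicit error guards the
zero-mean case; HU images can be used but invite near-zero denominators).
`ssim()` implements the single-window form — one mean, variance and
covariance over the whole ROI — with the conventional constants
`C1 = (0.01 L)²`, `C2 = (0.03 L)²`; `L` defaults to the joint value range
of both ROIs, which keeps the metric symmetric.  A sliding-window SSIM is
deliberately not provided: the implemented formula is the global one, and
mixing the two makes values incomparable.  The default ROI is a centred
square covering half of the FOV disk area.  Reported NMSE/SSIM values
always depend on ROI placement, so absolute values are only comparable
within one ROI convention — orderings are the meaningful comparison, and
those are what the experiment harness asserts.

## Numerical choices

* NMAR normalization is stabilized additively:
  `s_norm = (s + δ) / (prior + δ)` with `δ = 0.1 · max(prior sinogram)`.
  A multiplicative epsilon floor (`s / max(prior, ε)`) is the textbook
  form, but in small-FOV geometry the metal trace inevitably approaches
  the edge of the prior's support, where the prior sinogram vanishes
  while the target sinogram still carries streak and noise energy; the
  floored quotient then reaches ~1e5 and the denormalized reconstruction
  is unusable.  The additive form tends to `s / prior` where the prior is
  well supported and to 1 where both vanish, and it preserves both NMAR
  identities exactly: with a constant prior NMAR coincides with LMAR
  (linear interpolation commutes with affine maps), and with
  `prior = truth` the flattened sinogram is 1 across the trace, giving
  exact recovery.
* The prior's "soft tissue unaffected by artifact" is operationalized as
  soft-tissue pixels within 100 HU of the soft-tissue median; the source
  gives no rule.
* Zero counts are floored at 0.5 before the log; detector extension
  reflects with half-sample symmetry (the first synthesized sample copies
  the edge sample); ramp filtering pads to ≥ 4 native detector lengths;
  ties in the cosine-taper index bookkeeping follow the printed piecewise
  formula literally, with the extension taper clamped to zero past
  `N_ext` samples when `N_s > N_ext`.

## Problem sizes

Pipeline-level tests and the experiment harness default to a half-scale
conventional geometry (256 × 256 image, 360 views, 512 detector cells,
identical physical lengths and FOV), the package's chosen balance between
fidelity and turnaround for a 15-measurement, 60-reconstruction study;
projector-level accuracy tests run at the full 512 × 512 / 720-view
preset.  All orderings reported by `run_comparison()` are means over five
noise seeds.

## Known limitations

2-D fan-beam only (no cone-beam/FDK, no helical scans); no scatter or
detector blur; no iterative or learning-based MAR; the analytic spectrum
is a stand-in; absolute HU calibration under the polychromatic model is
approximate; and NMSE/SSIM absolute values depend on ROI placement.
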