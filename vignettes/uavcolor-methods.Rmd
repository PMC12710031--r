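---
title: "In-flight color correction of UAV crop imagery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-flight color correction of UAV crop imagery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavcolor)
```

## The problem

Aerial RGB imagery of crop canopies is used to quantify plant color —
a proxy for chlorophyll content, stress, and maturity. But the raw
pixel values of a drone camera confound the trait of interest with
illumination (clouds, sun angle), exposure settings, and
sensor-specific response. Without radiometric correction, the same
plot photographed an hour apart or with a different camera yields
different "colors", making measurements unusable across flights and
platforms.

The remedy implemented here keeps a physical reference — a 24-patch
ColorChecker Classic chart — visible in *every* frame (in the field
this is achieved by a second drone carrying the chart below the
imaging platform) and refits the correction *per frame*, so that each
image is corrected under exactly the lighting it was captured in.
`uavcolor` implements the complete computational pipeline: chart
detection, patch sampling, correction-matrix fitting, application,
masking for mosaicking, and evaluation — plus a synthetic-scene
generator so every stage is verifiable against ground truth without
any field data.

## The correction model

Let $A$ be the $n \times 3$ matrix of observed mean RGB values of the
$n \le 24$ usable chart patches and $C$ the corresponding reference
sRGB values. A bias column of ones augments the observations, and the
$4 \times 3$ color correction matrix $M$ solves the least-squares
problem

$$ C \approx [A \,|\, \mathbf{1}]\, M , \qquad
   M = (A^{\top}A)^{-1} A^{\top} C $$

with $A$ understood as the augmented matrix in the closed form. The
bias row absorbs additive offsets (haze, black-level differences)
which a pure $3 \times 3$ gain matrix cannot represent. Every pixel of
the frame is then mapped through $[r, g, b, 1]\,M$ and clipped to
$[0, 255]$. The model is deliberately linear: RGB distortions from
illumination and sensor gain are dominantly linear, and higher-order
polynomial fits, while better on the 24 patches themselves, extrapolate
poorly to colors outside the chart gamut.

Numerically the fit uses a QR factorization rather than the literal
normal-equations inverse (the closed form above is the definition, not
an implementation); a rank check rejects patch sets that are collinear
in color space. Patches with any channel mean strictly above 250 are
excluded as overexposed before fitting; the fit requires at least 6
usable patches and warns below 9, where correction accuracy is known
to degrade. The correction operates directly on stored (nonlinear)
sRGB values without linearization, matching how the reference values
are specified.

Color error is reported as CIEDE2000 ($\Delta E_{00}$, parametric
factors $k_L = k_C = k_H = 1$) between observed colors converted to
CIELAB (D65 illuminant, 2° observer) and the reference Lab values.
Values near 1 are at the threshold of human perceptibility; ~4–5 is a
practical acceptability limit. The implementation reproduces the
published 34-pair worked-example set to four decimal places
(`tests/testthat/test-colorimetry.R`).

## Chart detection

The chart is located by template matching: the user supplies a crop of
the chart from one representative frame, and each target frame is
searched by keypoint correspondence:

1. **Keypoints.** A difference-of-Gaussian scale-space detector with
   subpixel refinement, orientation assignment and 128-dimensional
   gradient-histogram descriptors (implemented in C++ in this package;
   the installed R stack has no keypoint-feature library). Descriptors
   use root-style normalization (L1 + square root), which improves
   discrimination on the chart's repetitive grid.
2. **Matching.** Brute-force nearest-neighbour descriptor matching
   with a Lowe ratio test (0.75; one retry at 0.85 if the first
   attempt cannot be validated), then a coarse consistency filter
   keeping the dominant mode of (scale ratio, rotation) among matches.
3. **Homography.** RANSAC (reprojection threshold 3 px) over the
   surviving correspondences, followed by guided re-matching around
   the initial estimate and a least-squares refit with tightening
   inlier bands (3 → 1.5 → 1 px).
4. **Validation.** The projected chart quadrilateral must be convex
   and non-degenerate, and the frame content must behave like a chart:
   the six neutral patches must decrease monotonically in luminance
   and each observed channel must correlate with the reference patch
   values across all 24 patches (r > 0.75) — orderings that survive
   any positive per-channel gain, so the check is robust to color
   casts while rejecting grid-shifted or spurious homographies.
5. **Sub-pixel polish.** Sample points on the known patch/gap edges
   are projected into the frame and snapped to the strongest
   outward-decreasing luminance gradient along each edge normal
   (parabolic sub-pixel interpolation); the homography is refit on the
   snapped points. On the synthetic benchmark this brings corner error
   from ~1.5 px down to ~0.5 px RMS.

Patch colors are then sampled on the inner 80% of each patch's
projected area — the linear side scale is $\sqrt{0.8} \approx 0.894$,
since 80% names an *area* fraction — which keeps the mean clear of
boundary noise. A pixel belongs to a sampling polygon iff its center
lies inside (half-open even-odd rule, so tiled polygons never double
count).

Detection failure (too few matches, no consensus, failed validation)
is a *result*, not an exception: batch runs record the frame and
continue.

## Brightness normalization and exposure

Illumination across a flight is tracked by the brightness of the 18%
gray patch (patch 22; mean of its three channel means), normalized to
a standard exposure condition (ISO 100, 1/100 s, f/8):

$$ L_{std} = L_{raw} \cdot \frac{ISO_{ref}}{ISO_{raw}} \cdot
   \frac{t_{ref}}{t_{raw}} \cdot \left(\frac{N_{raw}}{N_{ref}}\right)^2 $$

The aperture ratio enters squared with the *raw* f-number on top. This
is the physically consistent form for a sensor whose response scales
as $ISO \cdot t / N^2$: an image taken at a narrower aperture (larger
$N_{raw}$) is darker, so its reading must be scaled *up* to the
reference condition. The synthetic generator uses exactly this sensor
model, and the round trip (render at arbitrary exposure → normalize)
recovers the illumination profile, which the test suite verifies.

## Evaluation metrics

* **Cross-sensor consistency** treats each patch's measurements across
  cameras as a cluster in Lab space and reports the mean Euclidean
  distance of cluster members from their centroid (intracluster
  distance); correction should shrink it.
* **Leaf-area agreement** segments pixels whose $\Delta E_{00}$ to a
  ground-truth leaf color is strictly below a threshold (default 10)
  and reports the overlap ratio $|P \wedge T| / |T|$ against a
  ground-truth mask.
* **Plot color summaries** report mean RGB/Lab over a plot region and
  the normalized (R+B) index $(\bar R + \bar B)/(\bar R + \bar G +
  \bar B)$, computed on plot-mean channels. Chlorophyll absorbs red
  and blue, so greener (later-maturing) plots score lower. The index
  is invariant to uniform brightness scaling. The per-pixel-then-average
  alternative was rejected in favour of the plot-mean form, the standard
  chromaticity normalization; with typical within-plot variance the two
  differ far less than the cross-plot signal.
* **Fixed vs in-flight comparison** fits one CCM on a chosen reference
  frame and applies it to the whole series (the conventional single
  fixed chart), against refitting per frame. Under illumination drift
  the per-frame strategy dominates, and among fixed references the one
  whose illumination is closest to the series mean performs best —
  both orderings are reproduced on the synthetic drift benchmark.

## Mask generation for mosaicking

Since the chart (and its carrier) appears in every frame, it must be
masked before orthomosaic reconstruction. The detected quadrilateral
is expanded about its center *in chart axes* (via the homography, so
rotated charts expand correctly): 30% per direction along the long
axis and 50% per direction along the short axis, e.g. a 270 × 180 px
chart yields a 432 × 360 px mask. Overlap sufficiency is checked
against the flight plan: at 80% forward/side overlap and a
8192 × 5460 px sensor the overlaps are 4368 and 6554 px
(round-half-up), comfortably exceeding the mask, so neighbouring
frames fill the masked region. The long-axis extent follows from the
stated 30%-per-direction rule (270 × 1.6 = 432).

## The synthetic scene generator

The generator is first-class, tested code: it renders frames for which
every quantity the pipeline estimates is known exactly.

A scene consists of a flat soil-colored background (RGB 150, 120, 90),
leaf-like ellipses with colors drawn around a green center (means 70,
115, 50), and the 24-patch chart rendered at an arbitrary homography
with black inter-patch gaps and border, 2×2 supersampled at edges. The
radiometric model is

$$ I = \mathrm{clip}\big(g \odot (m \cdot I_{ideal}) + o + \epsilon\big),
   \qquad m = \text{illumination} \times \text{exposure response} $$

with per-channel gains $g$, offsets $o$, and additive Gaussian noise
$\epsilon$, quantized to 8 bits. With identity parameters the rendered
patches reproduce the reference colors exactly (up to quantization),
which anchors the whole benchmark.

Default study conditions (chosen once, used throughout tests and the
acceptance script):

| Parameter | Default | Rationale |
|---|---|---|
| frame size | 480 × 640 px | large enough for full pose range, small enough for fast suites |
| chart long axis | 270 px at scale 1 | the nominal in-frame chart geometry |
| chart scale range | 0.5–0.9 (benchmark) | half to nominal size |
| rotation | uniform ±180° | the chart carrier has no preferred heading |
| perspective jitter | ≤ 5% of chart size | near-nadir imaging geometry |
| channel gains | uniform [0.5, 1.0] | attenuation-only color cast, as in the color-distortion simulation |
| channel offsets | uniform [−10, 10] | black-level/haze scale on 8-bit data |
| noise σ | 1 (benchmark ≤ 2) | typical 8-bit sensor noise |
| drift series | 12 frames, 1.0 → 0.6 linear | 40% peak-to-peak, a strongly drifting sky |

The recovery benchmark additionally redraws gains/offsets until the
implied uncorrected patch error is at least ΔE 5, guaranteeing
distortions worth correcting.

What the generator does **not** emulate: directional (BRDF) leaf
reflectance, specular highlights, shadows, motion blur, demosaicing
artifacts, JPEG compression, or real canopy texture. Consequently a
passing synthetic suite demonstrates the *computational* correctness
of detection, fitting and evaluation — near-zero corrected ΔE under
exactly linear distortions — not the field accuracy of the method,
which on real imagery is limited by non-linear effects and by how well
a flat chart represents a 3-D canopy; corrected errors of a few ΔE
units, not near zero, are the realistic expectation there.

## Numerical choices and degenerate inputs

* Least squares via QR; rank < 4 is an error, not a silent pseudo-inverse.
* Overexposure threshold strict (`> 250` excluded, 250 retained).
* Corrected values clip to [0, 255]; the fit itself is unclipped.
* Round-half-up for overlap pixels (6553.6 → 6554).
* Pixel membership: half-open even-odd rule on pixel centers; polygon
  vertex order is irrelevant.
* Homography estimation normalizes coordinates (centroid 0, mean
  radius $\sqrt 2$) before the DLT for conditioning.
* RANSAC is seeded by the caller's RNG; all generator functions take
  explicit seeds and are bit-reproducible.
* The chart reference values are the widely published Classic sRGB
  coordinates (pre-2014 edition); the Lab companions stored in the
  packaged CSV were computed under D65/2° and agree with the package's
  own conversion to ΔE ≪ 0.1. The variant mechanism
  (`load_reference_chart()`) leaves room for the post-2014 edition.

## Problem sizes used in the shipped suites

The test and acceptance suites run the full detect → extract → filter
→ fit → apply pipeline on 50 distorted 480 × 640 frames, a 12-frame
drifting series for the strategy comparison, and 20 replicate
subset fits for the patch-count sensitivity — sizes at which the
complete suite runs in a few minutes on one CPU while still exercising
every code path at realistic chart geometry.

## Known limitations

* Per-frame correction only; no smoothing of CCMs across neighbouring
  frames (deliberate: each frame's chart sees that frame's light).
* One chart per frame; multi-chart frames are out of scope.
* Detection assumes the template and frame share broadly similar
  imaging conditions (the content validation tolerates strong color
  casts, but not, e.g., extreme defocus).
* JPEG input is supported for reading, but all outputs are lossless
  PNG to keep ΔE evaluation honest.
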