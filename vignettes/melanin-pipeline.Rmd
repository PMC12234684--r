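---
title: "Multi-contrast PS-OCT simulation and RPE-melanin quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-contrast PS-OCT simulation and RPE-melanin quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Melanin in the retinal pigment epithelium (RPE) scatters light in a way that
scrambles its polarization state. Polarization-sensitive OCT (PS-OCT)
quantifies this through the degree of polarization uniformity (DOPU), the
length of the locally averaged Stokes vector relative to the averaged
intensity: DOPU is 1.0 where the backscattered state is spatially uniform and
falls toward 0.0 where melanin randomizes it. Melanin, however, occurs both
in the RPE and in the choroid, so a depolarization map alone cannot isolate
the RPE. The melanin index fused here,

F_RPE = (normalized attenuation coefficient) x (1 - DOPU) x (1 - binarized angiography signal),

suppresses the choroidal contribution by exploiting the facts that the RPE
attenuates strongly and carries no blood flow. Counting voxels with
F_RPE >= 0.15 along each A-line and multiplying by the axial pitch yields an
en-face RPE-melanin thickness map; thresholding that map at 70 um delineates
thickened (active) RPE lesions, whose area can be related to the volume of a
serous pigment epithelial detachment (PED) computed from segmented surfaces
by the Cavalieri principle.

The package implements this entire chain, plus a *synthesis* route: a small
convolutional encoder-decoder is trained to predict DOPU B-scans from
standard (polarization-blind) OCT intensity B-scans, and the melanin pipeline
can then be driven by synthesized DOPU — the procedure that would let a
conventional OCT device produce melanin maps without polarization optics.
Because no public PS-OCT volumes with ground truth exist, the package also
contains a digital retinal phantom that generates every input with known
truth channels, making each stage testable end to end.

## The phantom

`generate_phantom()` builds a layered retina on a `[depth, aline, B-scan]`
grid (depth index 1 on the vitreous side):

* smooth undulating surfaces for the inner limiting membrane, an RPE melanin
  band of configurable thickness sitting on Bruch's membrane, the choroid,
  and a strongly scattering scleral base;
* an optional serous PED: a spherical-cap (or Gaussian) elevation of the RPE
  band off Bruch's membrane with low-scattering fluid beneath;
* per-voxel attenuation coefficients by layer (retina 1, RPE 6, fluid 0.2,
  choroid 2, sclera 12 mm^-1), with backscattered power proportional to the
  local attenuation so the depth-resolved attenuation estimator has a
  well-defined truth;
* fully developed speckle: each voxel's complex field is circular Gaussian
  with variance equal to the Beer-Lambert-attenuated reflectivity;
* polarization: all non-melanin tissue shares one global Jones state.
  Melanin voxels apply a per-voxel random SU(2) rotation whose Haar-random
  rotation angle is scaled by `scramble_p` (0 = no scrambling, 1 = states
  uniform on the Poincare sphere). The choroidal stroma scrambles with a
  separate, weaker strength (default 0.4 versus 0.9 in the RPE), reflecting
  the qualitative observation that choroidal depolarization is present but
  the quantitative relation between melanin density and DOPU is not
  established;
* choroidal vessels: contiguous ellipsoidal lumens (roughly 60-130 um
  diameter) are placed until `flow_fraction` of the choroid is vascular.
  Vessel voxels redraw their speckle independently for every repeat; static
  voxels reuse one speckle realization across the four repeated B-scans,
  with fresh additive complex Gaussian detector noise per repeat and
  channel. Noise power is calibrated so the RPE band sits at `snr_db`.

The default grid is 64 B-scans x 128 A-lines x 256 depth pixels over a
nominal 6.0 x 6.0 mm scan at 4.0 um axial pitch — a half-resolution version
of the modelled scanner's 256 x 512 raster, chosen so one volume occupies
about 270 MB of complex data and generates in roughly ten seconds; the
full-scale geometry is available through the configuration. Four repeats are
generated per B-scan location, matching the repeated-scan protocol that
angiography requires.

What the phantom does *not* emulate: ocular aberrations and defocus, motion
artifacts, vignetting, multiple scattering, projection artifacts beneath
vessels, and any quantitative melanin-concentration-to-DOPU calibration.
Passing tests on the phantom therefore demonstrate the correctness and
internal consistency of the estimators under their own model assumptions,
not clinical performance.

`generate_cohort()` draws per-subject randomized configurations; it returns
configurations rather than volumes so an arbitrarily large cohort can stream
through the pipeline one ~270 MB volume at a time (`subject_volume()`
materializes one subject; `materialize = TRUE` keeps them all for small
cohorts).

## Polarimetry

`compute_stokes()` forms S0..S3 per voxel from the two detection channels
and averages repeats (a flag keeps a single repeat for ablation, since it is
not established whether averaging should precede windowing). `compute_dopu()`
averages Stokes components over a 3 x 3 (depth x A-line) kernel inside each
B-scan, applies the additive-noise bias correction — subtracting the total
noise power from the averaged S0 and the channel-power difference from S1 —
and takes the corrected polarization-vector length over corrected S0,
clipped to [0, 1]. Windows are truncated at volume borders rather than
padded, so edge estimates average only real data. Voxels whose corrected S0
falls at or below `s0_floor` (default three times the total noise variance)
are invalid: they carry NA, are excluded from statistics, and force
F_RPE = 0 downstream. The kernel is confined to one B-scan because repeated
B-scans exist only within a scan location.

`coherent_composite()` estimates each repeat's bulk phase against the first
repeat per A-line (argument of the complex inner product over depth and both
channels), rotates it out and averages complex fields, which lowers the
additive noise floor by about the repeat count while leaving static speckle
untouched.

## Attenuation and angiography

The depth-resolved attenuation estimator divides each voxel's intensity by
twice the pitch times the remaining intensity below it. Two numerical
choices matter:

* **Speckle averaging.** Single-voxel OCT intensity is exponentially
  distributed, so the raw ratio fluctuates with ~100% relative error. The
  intensity is averaged over a 5 x 15 (depth x A-line) window first — about
  75 speckles, bringing the median relative error below 10% in
  homogeneous tissue. The window is deliberately wide transversely and
  short axially to preserve depth resolution at the thin RPE band.
* **Tail completion.** The estimator assumes all remaining signal lies
  inside the scan; signal leaving through the bottom inflates the deepest
  estimates. The terminal per-pixel decay rate is estimated from the last
  fully windowed rows, pooled as a median across the volume, and the tail
  sum is completed as a geometric series. The composite's residual noise
  floor (total noise variance divided by the repeat count) is subtracted
  before estimation so a flat noise floor is not mistaken for a
  non-decaying tail. The bottom `tail_cutoff_px` rows (default 16) remain
  invalid regardless.

Inside vessels the composite intensity is additionally washed out — averaging
four independent speckle realizations coherently destroys ~3/4 of the power —
so attenuation under-reads in flowing blood. This is inherent to motion
contrast, is documented rather than corrected, and does not affect F_RPE
because those voxels are excluded by the flow factor anyway.

Angiography computes, per channel and adjacent repeat pair, the
noise-corrected complex correlation over a 3 x 3 kernel (window counts track
the truncated borders), averages correlation magnitudes over pairs and
channels, and reports decorrelation = 1 - correlation, binarized at 0.30 by
default. Bulk phases from the composite are removed first so axial bulk
motion cannot masquerade as flow. Voxels whose noise-corrected denominators
are nonpositive are treated as static — at depth, where noise dominates, the
angiogram is deliberately conservative.

The attenuation normalization constant `mu_ref_mm1` (default 10 mm^-1) makes
the first F_RPE factor dimensionless so the 0.15 voxel threshold is
meaningful; the native scale of that threshold in the original formulation is
not recoverable from the published material, so both the constant and the
threshold are explicit configuration with defaults.

## Melanin quantification

`compute_frpe()` forms the exact three-factor product, zeroing any voxel
invalid in DOPU or attenuation. `thickness_map()` counts suprathreshold
voxels per A-line — deliberately without a contiguity requirement, since the
definition is a pixel count; a flag restricts counting to the longest
contiguous run for sensitivity analysis. Thickness is reported as count
times pitch with no sub-pixel interpolation. `lesion_area()` is exact pixel
counting of the >= 70 um mask, optionally restricted to a PED-margin region
of interest (the phantom supplies it from truth; for real data it is a
drawn polygon). `ped_volume()` sums per-B-scan cross-sectional areas between
the detached RPE base and Bruch's membrane times the B-scan spacing
(Cavalieri). `transverse_scale()` applies a Bennett-style axial-length
correction, (AL - 1.82)/(24.46 - 1.82), to both transverse pitches; areas
therefore scale by its square. Axial distances are never rescaled, so the
70 um threshold applies to all eyes identically — the conventional choice,
since the axial scale of OCT is set by the light source, not ocular
magnification.

## DOPU synthesis

The synthesis network is a three-level U-Net-style encoder-decoder
(3 x 3 convolutions + ReLU, 2 x 2 average pooling, nearest-neighbour
upsampling, skip connections, sigmoid output; default widths 8/16/32, about
60k parameters), implemented directly on BLAS matrix products with exact
analytic gradients (verified against finite differences in the test suite).
Average pooling was chosen over max pooling for its exact, smooth backward
pass; DOPU targets are themselves kernel-averaged and smooth. Training
minimizes per-pixel binary cross-entropy — DOPU lies in [0, 1] and is treated
as a Bernoulli mean — restricted to valid voxels by a mask; mean squared
error is available as an ablation. Adam with learning rate 2e-3, batch 8 and
the best-validation checkpoint are the defaults.

Inputs are per-volume normalized: log-scaled intensity mapped affinely to
[0, 1] by its robust 1st/99th percentiles, identically at training and
inference. Patches (default 64 x 64) tile selected B-scans; the subject-wise
8:2 split is enforced structurally (a subject cannot appear in both splits).
Inference tiles each B-scan with 50% overlap and uniform averaging to avoid
seams, clips to [0, 1], and inherits a validity mask from the intensity
floor.

Note that the network's BCE has a nonzero floor — the mean pixelwise entropy
of the DOPU targets themselves (approximately 0.3 on the phantom cohort) —
so training curves flatten well above zero even as the mean absolute error
keeps improving. Held-out performance on the phantom (MAE < 0.1, map
correlation r > 0.8 against measured-DOPU maps) mirrors the qualitative
original-versus-synthesized agreement reported for clinical data, including
the systematic under-reading of thickness by the synthesized route; it does
not certify clinical transfer, which would require training on real scanner
data.

## Problem sizes used by the tests and reports

The test suite exercises the pipeline at the sizes the package's own study
conditions define: a 20-eye cohort at the default 64 x 128 x 256 geometry,
20 dB RPE SNR and scramble 0.9 for parameter recovery (thickness-map median
error within one axial pixel, recovered-versus-truth correlation above 0.9,
spherical-cap PED volume within 3% of the closed form); and a 12-subject
cohort at 32 B-scans per volume for the synthesis procedure (8:2 subject-wise
split, 8 epochs over 768 patches). The reduced B-scan count for the
synthesis cohort trades no statistical structure away — every B-scan is an
independent realization of the same layered scene — and keeps the cohort's
two full passes (training data and per-eye evaluation) to a single volume
generation each.

## Degenerate inputs, tie-breaks, tolerances

* All-noise or signal-free A-lines: invalid in attenuation (empty tail) and
  DOPU (S0 floor); F_RPE is zero there by construction.
* Angiography with a single repeat is rejected; a repeat pair whose
  corrected denominators are nonpositive is static, not flow.
* Wilcoxon signed-rank comparisons use the exact distribution for n <= 25
  except in the presence of ties or zero differences, where the normal
  approximation is used (the exact distribution is undefined); with all-zero
  differences the test degenerates to "no difference" (p = 1).
* Pearson correlations are undefined (NA) for zero-variance vectors.
* Fewer than 5 pairs: descriptive statistics only, with a warning.
* Seeds fix everything: phantom volumes bit-for-bit, cohort draws, the
  subject split, weight initialization and batch shuffling; single-threaded
  runs are byte-reproducible.

## Known limitations

* `scramble_p` is an abstraction of melanin-induced depolarization, not a
  calibrated melanin concentration; the mapping between the two is an open
  experimental question.
* The phantom's layer optical properties are plausible round numbers, not
  fitted to measurements at the modelled 1.0 um wavelength.
* The attenuation estimator assumes single scattering and backscatter
  proportional to attenuation; the phantom satisfies this by construction,
  real tissue only approximately.
* The synthesis model is deliberately tiny and trained on synthetic data;
  its clinical-scale counterpart and training corpus are out of scope.
* No automatic segmentation: PED surfaces come from truth channels (or, for
  real data, external segmentation), matching the manual segmentation used
  in practice.
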