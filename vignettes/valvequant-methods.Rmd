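---
title: "Quantifying fibrotic aortic valve disease from marker-free imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrotic aortic valve disease from marker-free imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvequant)
```

## The problem

Aortic valve sclerosis in mouse models (hyperlipidemic ApoE-deficient
animals vs. wild type) manifests as leaflet thickening, collagen loss and
disorganization, and lipid accumulation. `valvequant` quantifies these
from three marker-free modalities — second-harmonic generation (SHG,
fibrillar collagen), coherent anti-Stokes Raman scattering (CARS, lipids
at the CH₂ stretch), and optical coherence tomography (OCT, leaflet
geometry) — plus picrosirius-red histology as the conventional reference.
Leaflets are analyzed in three regions: region 1 is the free edge of the
tip (nodulus), region 2 the middle, region 3 the base/annulus.

This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions taken where
the procedure left genuine freedom.

## Collagen quantification from SHG with crystal correction

Per slice, the SHG image is

1. smoothed with a **mean filter of radius 1 px** — read as the 3×3
   square neighborhood with edge replication and integer rounding. A disc
   kernel of radius 1 is an alternative reading of "radius"; at radius 1
   the choice is immaterial for fibers wider than a pixel, and the square
   kernel is what the brute-force oracle tests pin down;
2. linearly stretched to the full 16-bit range with **0.4 % saturated
   pixels**, split 0.2 % per tail: with *n* pixels,
   *k* = ⌊*n* · 0.4/200⌋ pixels clip at each end and the (*k*+1)-th
   order statistics map to 0 and 65535. A constant image is returned
   unchanged (the stretch is undefined there; identity is the only
   self-consistent choice);
3. binarized at intensity **strictly above 20 000 counts** ("above a
   threshold" read literally; the boundary behavior is unit-tested).

Cholesterol crystals are SHG-active, so raw SHG area overstates collagen.
The matching CARS slice is smoothed and stretched the same way, then
background-subtracted with a **top-hat**: grayscale opening by a flat
disc of radius 30 px subtracted from the image, the deterministic
equivalent of rolling-ball background subtraction for a flat structuring
element. (Whether the original interactive analysis used the paraboloid
"rolling ball" or morphological opening is not determinable; we
standardize on opening because it is exactly reproducible and
oracle-checkable. The opening itself is EBImage's grayscale morphology,
verified bit-exact against a pixel-loop reference.) The **triangle
threshold** (Zack) is then computed on a 256-bin histogram of the 16-bit
range (bin = intensity ÷ 256): a line is drawn from the histogram peak to
the farthest nonzero bin on the longer-tail side, and the threshold is
the bin of maximum perpendicular distance; the mask is "bin strictly
above threshold". Objects must be bright; the histogram is used as-is.
A constant (lipid-free) CARS image has no definable threshold — callers
treat that as "no lipid detected".

The pixel-wise product of the two binary images isolates doubly-active
structures, i.e. the crystals, and

corrected % = area%(SHG) − area%(SHG ∧ CARS) = area%(SHG ∧ ¬CARS),

which is non-negative by construction and satisfies
corrected + crystal = raw exactly. Per-slice corrected percentages are
averaged over the stack per leaflet region. The area denominator is the
whole image by default (images are acquired inside tissue); a leaflet
mask denominator is available. The "visual inspection of the binary
images" step of an interactive workflow becomes an optional QC dump of
the per-slice masks as 8-bit TIFFs.

### Detection bias at object boundaries

The fixed 20 000-count threshold sits at 30.5 % of the stretched range,
so the detected boundary of a bright object lies where the smoothed
anti-aliased edge profile crosses ≈0.3 rather than 0.5 — a systematic
halo of roughly half a pixel around the brightest objects. For fibers
(intensity ≈0.6 of the stretched maximum) the crossing is almost exactly
at the half-coverage contour and the area estimate is nearly unbiased;
for saturating crystals the halo adds ≈0.3–0.5 percentage points per
percent of crystal perimeter. This scales with the perimeter-to-area
ratio, which is why the phantom's crystals default to plate-like
dimensions (12.6 × 2.5 µm at the 0.28 µm pixel pitch) matching the
morphology of tissue cholesterol crystal plates.

## Fiber orientation: structure-tensor coherency

Gradients are taken with Gaussian derivative kernels (σ = 1 px default;
the OrientationJ-style analysis this mirrors does not fix the kernel
family — cubic-spline gradients are the common alternative — so Gaussian
derivatives are used and documented). Borders are handled by symmetric
(reflective) padding. The tensor components Jxx = ⟨IxIx⟩, Jxy = ⟨IxIy⟩,
Jyy = ⟨IyIy⟩ are **averaged over the whole subregion** (energy-weighted
single tensor) rather than averaging per-pixel coherencies: one coherency
is reported per subregion, and the energy weighting keeps low-signal
pixels from dominating. Then

C = (λ₁ − λ₂) / (λ₁ + λ₂),  λ₁ ≥ λ₂ ≥ 0,

with C defined as 0 when λ₁ + λ₂ = 0 (constant region). C = 1 for
perfectly parallel structure, 0 for isotropic texture. The dominant fiber
angle is the minor eigenvector direction (perpendicular to the mean
gradient), reported in degrees in [−90, 90), counter-clockwise from the
image x-axis.

Because collagen runs circumferentially to the annulus, the preferred
direction differs between the two halves of a leaflet image; images are
split at ⌊width/2⌋ (odd middle column to the left half) into subregions
*r*.1 and *r*.2. Which stack slice to analyze is not prescribed; the
middle slice is the default, configurable.

## OCT morphometry

OCT's axial and lateral resolutions are independent, so volumes are first
resampled to **isotropic 2.255 µm voxels** by trilinear interpolation
(sequential per-axis linear interpolation; sample points sit on original
voxel centers, preserving extent within one voxel). OCT measures optical
path length; geometric depth is optical path divided by the refractive
index, fixed at **n = 1.33** (water) since all comparisons are relative
and valve tissue's true index (1.33–1.44) is unknown. The package applies
the optical→geometric correction *before* the isotropic rescale, so one
resampling pass yields geometric isotropic voxels; the order is not
prescribed by the source procedure and the alternative (rescale in
optical units first) differs only by a second interpolation. A 100 µm
band at n = 1.33 spans 133 µm of optical path; the correction restores
100 µm.

To raise contrast and SNR, **ten adjacent cross-sections are summed**
(not averaged; the widened dynamic range is intentional), centered on the
requested slice. Leaflet area is mask pixel count × pitch². Thickness is
measured along rays perpendicular to the base→tip axis: mask pixels are
binned by their projection onto the axis (bins one pitch wide) and the
bin's thickness is its pixel count × pitch — total chord length, robust
to mask roughness, speckle holes and rotation. Per region the default
aggregate is the **mean** over bins (a single-line measurement cannot be
reproduced deterministically; the mean is robust), with a max-chord mode
available. Regions are assigned by splitting the projected extent into
three equal intervals, tip-most third = region 1 — the regular grid
reading of the region scheme. Phantom volumes are segmented by Otsu's
threshold on the composite cross-section (largest 8-connected component);
real-data masks come from manual segmentation and are supplied as inputs.

## Histology

Collagen fraction on picrosirius-red sections uses color deconvolution:
per-channel optical density OD = −log₁₀((I+1)/256), unmixed by inverting
the stain matrix, concentrations clipped at zero. The original stain
vectors are not published, so the defaults are Ruifrok–Johnston-style
vectors (fast-red-type vector for picrosirius red, hematoxylin
counterstain, normalized cross product as residual), overridable per
slide set. The "manually defined threshold" is deliberately a required
configuration value with a QC overlay — reproducible emulation of a
manual step — so results on real slides depend on that calibration;
phantoms are the quantitative acceptance surface. Section area and
thickness reuse the OCT measurement operators (source tag HISTOLOGY), so
identical masks give identical numbers across modalities.

## Statistics

Group comparisons (n = 6 per group in the motivating study) are gated by
a per-group Kolmogorov–Smirnov normality test. Since the normal
parameters are estimated from the sample, the **Lilliefors-corrected**
variant is the default (`nortest::lillie.test`; the classical KS test
against N(x̄, s) is available, and is the fallback for n < 5 where the
Lilliefors implementation is undefined). If both groups pass (p > α),
the **one-tailed unpaired Student t-test** (equal variances) is used;
if either fails, the **one-tailed Mann–Whitney U** — the conservative
per-group reading of the routing rule. The one-tailed direction must be
pre-specified explicitly per metric; nothing infers it from the data.
α = 0.05; summary tables carry the star tiers *P ≤ 0.05, **P ≤ 0.01,
***P ≤ 0.001. No multiple-testing correction is applied, matching the
source analysis.

## The phantom generators

Phantoms stand in for the animals; their defaults encode the acquisition
geometry of the motivating study: MPM stacks of 14 slices, 500 × 500 px
at 0.28 µm/px (140 µm field), 16-bit; OCT volumes with anisotropic pitch
and an axial axis in optical units; three-region thickness profiles
defaulting to (137, 90, 80) µm — the sclerotic tip thickening over a
normal middle and base.

* **Fibers** are straight anti-aliased segments (width 3 px ≈ 0.8 µm,
  the scale of collagen fiber bundles at this resolution) with
  orientations from a von Mises distribution on the doubled-angle circle:
  κ = 0 is axially uniform, large κ parallel; fibers are added until the
  target area fraction is reached (bounded attempts, then an error).
  Straight segments suffice for area-fraction and coherency ground truth;
  fiber curvature is out of scope.
* **Lipid droplets** (CARS-only discs) and **cholesterol crystals**
  (plate-like segments rendered at high intensity into BOTH channels —
  the property the correction exploits) are volumetric: positions are
  drawn once per phantom with a minimum separation so that counts are
  well defined, and rendered into every slice. Fibers never cross droplet
  footprints (lipid pools displace the mesh), and the visible-collagen
  truth excludes crystal footprints (crystal signal dominates anything
  beneath).
* **Truth masks are recorded before noise**; the recorded fractions equal
  mask pixel counts exactly.
* **Noise**: Poisson shot noise on signal (0.05 photons/count) plus
  additive Gaussian read noise (SD 500 counts) over a 1000-count
  baseline, then 16-bit quantization — a generic photon-counting
  detector model. The study reports no SNR figures, so these defaults
  are chosen for testability at a realistic-looking noise level, not
  fidelity to a particular instrument.
* **OCT speckle** is multiplicative Rayleigh with unit mean (first-order
  speckle statistics), mixed at contrast 0.6; the band's axial extent is
  geometric thickness × n, emulating optical-path measurement.
* **Histology phantoms** render collagen blobs with the red-stain OD
  vector over a uniform counterstain via Beer–Lambert mixing and the
  8-bit transmittance model I = 256·10^(−OD) − 1.

What phantom-based validation does **not** show: performance under real
point-spread functions, depth-dependent attenuation, residual melanin
artifacts,
stain variability, or manual-segmentation variability. Phantoms validate
the computational chain, not the instruments.

## Problem sizes used in the tests

The test-suite and the acceptance script run the generators at reduced
geometry — 128 × 128 px MPM slices with 1–3 slices per stack,
160 × 24 × 150-voxel OCT volumes, 192 × 192 histology sections — chosen
so the full validation (including 60 collagen-recovery phantoms, 120
coherency phantoms, 10 OCT chains and 5000 statistical null simulations)
completes in a few minutes while leaving every tolerance comfortably
met. The defaults of the generators themselves remain at the study's
full acquisition geometry.

## Numerical conventions and degenerate inputs

* Percentages are always in [0, 100]; area denominators are explicit.
* Threshold comparisons are strict (`>`); boundary cases are unit-tested.
* Constant images: identity under stretch, error under triangle
  threshold (mapped to "no lipid"), zero tensor and C = 0 under
  coherency.
* Empty masks: area 0 with a warning; regions without pixels give NaN
  thickness; the SD of a single animal is NaN and serialized as such.
* Seeds: all generators are deterministic given (spec, seed), with
  independent substreams per slice and per structure class so that
  raising the fiber density extends, rather than reshuffles, the fiber
  set (this is what makes truth fractions monotone in the density).

## Known limitations

* The 20 000-count SHG threshold is an absolute count on stretched
  images; its biological calibration came from the original instrument
  and must be re-validated per setup.
* Crystal/droplet classification in the lipid summary uses a 50 %
  SHG-overlap rule on 8-connected components with a 9 px minimum
  component size; touching structures merge.
* Real-data leaflet segmentation (OCT and histology) is manual by
  design; only phantom segmentation (Otsu) is automated.
* Histology results depend on the supplied stain vectors and OD
  threshold; they are reproducible given a config, not absolute.
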