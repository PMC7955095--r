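# valvequant

Marker-free quantification of fibrotic aortic valve disease from
multiphoton and OCT imaging of murine valve leaflets.

Aortic valve sclerosis — fibrotic thickening of the valve leaflets without
outflow obstruction — is the precursor of calcific aortic stenosis.
Studying its onset in mouse models (hyperlipidemic ApoE⁻/⁻ vs. wild type)
requires quantifying leaflet geometry, collagen content and architecture,
and lipid accumulation without stains or markers. `valvequant` implements
the full quantitative chain for three marker-free modalities plus the
histological reference:

* **SHG collagen quantification with cholesterol-crystal correction.**
  Per slice of a second-harmonic-generation stack: mean filter (radius
  1 px) → linear min–max contrast stretch (0.4 % saturated pixels) →
  fixed threshold (intensity > 20 000). Cholesterol crystals are also
  SHG-active, so the matching CARS slice (smooth → stretch → top-hat
  background subtraction, disc radius 30 px → triangle threshold) is
  binarized and multiplied with the SHG mask; the doubly-active area
  (the crystals) is subtracted:

  `corrected % = area%(SHG) − area%(SHG ∧ CARS) = area%(SHG ∧ ¬CARS)`

  Stack results are averaged per leaflet region (1 = tip, 2 = middle,
  3 = base).
* **Collagen fiber orientation order** via the structure tensor:
  Gaussian-derivative gradients, region-averaged tensor J, coherency
  `C = (λ₁ − λ₂)/(λ₁ + λ₂) ∈ [0, 1]` (1 = perfectly parallel fibers,
  0 = isotropic), computed on the left/right halves of each region image.
* **OCT morphometry.** Trilinear rescaling to isotropic 2.255 µm voxels,
  optical→geometric axial correction (geometric depth = optical path /
  n, n = 1.33), 10-slice composite cross-sections, and mask-based leaflet
  area (pixels × pitch²) and region-wise thickness (projected-bin chord
  lengths along the base→tip axis).
* **Picrosirius-red histology.** Color deconvolution
  (OD = −log₁₀((I+1)/256), stain-matrix inversion) and a manually
  specified OD threshold give the collagen-positive area fraction;
  section morphometry reuses the OCT operators.
* **Group statistics.** Kolmogorov–Smirnov (Lilliefors) normality gate per
  group; one-tailed unpaired Student t-test when both groups pass,
  otherwise one-tailed Mann–Whitney U; star tiers `*P ≤ 0.05`,
  `**P ≤ 0.01`, `***P ≤ 0.001`.
* **Phantom generators** for all modalities with exact ground truth
  (collagen/crystal fractions, droplet counts, von Mises orientation
  concentration, leaflet thickness profiles), so every stage is testable
  end to end without imaging data.

## Worked example

```r
library(valvequant)

# synthetic SHG/CARS stack: 10 % collagen, 2 cholesterol crystals
ph <- generateMPMPhantom(sizePx = c(128, 128), nSlices = 3,
                         fiberDensity = 0.10, crystalCount = 2, seed = 1)
ph$truth@collagenFractionPct
#> [1] 10.42074

res <- collagenStack(ph$shg, ph$cars)
res
#> CollagenResult (region ?): mean 10.03% over 3 slice(s), crystal-corrected
```

The corrected collagen fraction (10.03 %) recovers the planted truth
(10.42 %) to within a fraction of a percentage point; the difference is
detection noise at fiber edges. OCT morphometry on a speckled phantom
volume:

```r
oc  <- generateOCTPhantom(seed = 1)          # 137/90/80 um regions, n = 1.33
vol <- rescaleIsotropic(opticalToGeometric(oc$volume), 2.255)
cs  <- compositeCrossSection(vol, dim(voxels(vol))[2] %/% 2, window = 10)
mask <- segmentCrossSection(cs, 2.255)
leafletMorphometry(mask, tipPoint = c(269, 59), basePoint = c(16, 59))
#> MorphometryResult [OCT]: area 58869 um^2; thickness region1 = 136.9 um,
#>   region2 = 90.2 um, region3 = 80.0 um
```

The recovered thickness profile (136.9, 90.2, 80.0 µm) matches the
planted (137, 90, 80) µm within a third of a voxel, and the area is
within 0.2 % of truth — after the 1.33-fold optical-to-geometric
correction, without which region 1 would read ~182 µm.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/valvequant.R`
(`Rscript valvequant.R <simulate|mpm|coherency|oct|histo|stats> ...`).

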