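---
title: "Whole-slide mIHC tissue cytometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide mIHC tissue cytometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis problem

Multiplexed immunohistochemistry (mIHC) platforms that combine a
five-channel fluorescence acquisition (nuclei plus up to four antibody
markers) with a three-chromogen brightfield acquisition of the *same*
section can read out six protein markers per cell across a whole slide.
Turning the two gigapixel acquisitions into a per-cell table requires a
chain of image operations: the two modalities must be registered onto one
grid, the chromogens separated into per-stain concentration maps, glands
and nuclei segmented, marker intensities quantified per nucleus, and every
cell assigned to a biological class. `wsicyto` implements that chain,
together with a synthetic-slide generator that provides ground truth for
every stage, so the whole pipeline can be validated by parameter recovery
rather than by eye.

Two classification schemes are built in, modelled on prostate-cancer
panels:

* **immune scheme** — CD45 identifies leukocytes; CD4, CD8 and FoxP3
  subtype them into T regulatory (CD4+FoxP3+CD8-), T helper
  (CD4+FoxP3-CD8-) and T effector (CD8+CD4-FoxP3-) cells; the
  pan-epithelium signal (Pan-CK + E-cadherin) defines the epithelial
  compartment, so each T class is counted separately inside glands and in
  the stroma; Ki67 measures proliferation.
* **epithelial scheme** — glands are classified benign or malignant by the
  presence or complete absence of CK5+p63 basal cells (the loss of the
  basal layer being the diagnostic hallmark of prostate cancer); epithelial
  cells become basal, benign luminal or cancer cells, and AR, AMACR, CK8,
  CK18 expression is measured per cell.

# Models and procedures

## Colour de-convolution

Chromogen absorbances mix linearly in optical-density space
(Beer–Lambert): for RGB channel $k$,
$\mathrm{OD}_k = -\log_{10}(I_k/255) = \sum_s c_s M_{sk}$, where the rows
of $M$ are the unit-norm colour vectors of the stains. `deconvolve()`
inverts $M$ per pixel after an area-averaging downscale (default 1:4) and
clips negative concentrations to zero (the clipped fraction is reported).
The haematoxylin vector uses the published reference values; the green and
red chromogen vectors of the development fixtures are *synthetic
stand-ins* (`synthetic_stain_matrix()`) because real chromogen vectors are
batch-dependent and must be supplied by the user. The OD conversion clamps
intensities at 1 to keep OD finite.

## Registration

Both modalities image the same nuclei, so the haematoxylin concentration
map (reference) and the fluorescence nuclear channel (moving) are aligned
by blob features: a scale-normalized determinant-of-Hessian detector over
a fixed scale ladder (1.6–6.7 px, factor 1.33) with quadratic sub-pixel
localisation, upright SURF-style 64-dimensional descriptors (4×4 cells of
Gaussian-weighted gradient sums), Lowe-ratio (0.75) plus mutual
nearest-neighbour matching, and a 2000-iteration random-sample-consensus
affine fit (2 px inlier threshold, fixed internal seed) refined by least
squares on the consensus set. Descriptors are deliberately *upright*
(not orientation-steered): slide-to-slide rotations in this setting are a
few degrees, well inside the operating range of upright descriptors, and
skipping orientation estimation removes one noise source.

Working resolutions default to 1.76 µm/px (haematoxylin) and 2.56 µm/px
(nuclear channel), and all channels are resampled onto a common 0.64 µm/px
grid in the brightfield frame, with bilinear interpolation and 8-bit
re-quantization. Coordinates are handled with an explicit pixel-centre
convention (pixel $i$ sits at $(i+0.5)\,\mathrm{res}$ µm), which keeps the
composed grid transforms sub-pixel exact; on synthetic pairs the recovered
transform agrees with the planted one to well under 1 px RMS on the
0.64 µm grid.

## Tiling and stitching

Slides are processed in square core tiles (default 2048 px) that partition
the slide exactly — half-open pixel intervals, 0-based origins — each
embedded in a centred context window (default 10240 px, zero-filled beyond
the slide) so that any gland intersecting a core is seen whole by that
tile. Objects are kept by the tile whose half-open core contains their
centroid; this rule alone guarantees every cell is counted exactly once,
including cells sitting exactly on a shared boundary. Gland malignancy is
decided per tile from the full context, so glands crossing core borders
are never judged from a fragment.

## Segmentation

* `otsu_level()` is the classic two-class, 256-bin histogram threshold
  maximizing between-class variance on raw intensities, ties broken toward
  the lower level; foreground is *strictly above* the level.
* `adaptive_otsu()` computes the level per block (default 200 px) and
  interpolates bilinearly between block centres, which handles non-uniform
  background; a window larger than the image falls back to the global
  level.
* A *minimum class-contrast guard* (default 16 gray levels) protects both
  thresholding paths and `marker_mask()`: a histogram whose two Otsu
  classes separate by less than the guard is background-only, and
  thresholding it would only carve up noise — such regions yield no
  foreground. The default is roughly eight times the generator's noise SD
  and far below any real mode separation (~100 gray levels).
* Nuclei: adaptive Otsu, hole filling, declumping by seeded region growing
  from smoothed intensity peaks (Gaussian σ = 2 px; minimum peak
  separation = the minimum accepted diameter), then removal of objects
  whose equivalent-circle diameter $2\sqrt{A/\pi}$ leaves the 20–80 px
  acceptance band.
* Glands: Otsu (global for the immune panel, adaptive for the epithelial
  panel), morphological closing (radius 10 px) to bridge the epithelial
  cell ring, hole filling so lumina count as gland interior, and
  distance-transform watershed to split touching glands. The watershed
  split decision is made on a 4× subsampled grid (gland geometry spans
  hundreds of pixels, so the coarse distance map carries the same maxima);
  only components the coarse pass actually divides are re-run at full
  resolution — a pure speed optimisation whose result is the full-res
  watershed wherever it matters. Objects below 500 px² are dropped as
  speckle.

## Quantification and classification

Marker intensity is the mean 8-bit intensity over the nucleus pixels,
normalized as raw/255 — a single global scale, chosen over per-marker
min–max because absolute expression levels must stay comparable across
classes. A cell is positive when its normalized value is strictly above
mean + k·SD over *all* cells (population SD; k = 1, Ki67 k = 3 to protect
the rare-positive regime). Mask-derived calls (CD45, CK5+p63) use
nucleus-area overlap with the marker's global-Otsu mask, with a 10%
minimum — the one overlap fraction the workflow defines, reused for CD45
for symmetry. Compartment is centroid containment in the hole-filled gland
mask, a single deterministic rule for boundary-straddling cells. Gland
lumina count as "inside".

The immune rules map (CD45, CD4, CD8, FoxP3, compartment) onto a closed
ten-label set; CD45+ cells matching none of the three T-cell definitions
are `leukocyte-other` (forced by rule exclusivity). The epithelial rules
classify glands first (malignant iff zero basal cells), then cells.

## Statistics and QC

`fisher_exact_2x2()` uses the probability-mass two-tailed rule (the sum of
hypergeometric probabilities of tables no more probable than the observed
one, with a 1e-7 relative tie guard). `ks_two_sample()` computes the exact
ECDF supremum and an asymptotic Kolmogorov p-value at effective size
$nm/(n+m)$ — appropriate at whole-slide sample sizes; an exact small-sample
p is out of scope. `pearson_r()` is the product-moment coefficient with a
t-transform p-value. `signal_to_background()` implements
$(\bar S - \bar B)/\bar B$ with a 1000-pixel background minimum; its
`noise_threshold` flag (off by default) excludes signal pixels at or below
the background's Otsu level — our interpretation of background-noise
thresholding, clearly labelled as such. `heat_retention()` segments
objects on the pre-heating image (Otsu, dilation, watershed), keeps
objects strictly larger than 100 px, and reports the post/pre ratio of
mean object intensities.

# The synthetic-slide generator

`generate_slide()` emulates the paired acquisition so that every
downstream stage has a parameter-recovery oracle:

* **Tissue geometry.** Elliptical glands (semi-axes 80–130 px at
  0.64 µm/px, i.e. glands ~100–170 µm across — typical prostate acini) are
  placed on a jittered hexagonal grid whose spacing guarantees
  non-overlap. Epithelial cells occupy a jittered hexagonal site lattice
  in the gland annulus; benign glands additionally carry a basal ring at
  0.94 of the gland outline with a clear band below it; lumina are empty
  except for infiltrating leukocytes (immune scheme). Stromal cells use a
  sparser lattice with a clearance band around every gland. The site
  lattices guarantee minimum cell separations (≥ ~25 px), below which
  nuclei would merge under any segmentation — the generator emulates
  moderately packed tissue, not maximally confluent sheets (a stated
  limitation).
* **Cells.** Isotropic Gaussian blobs, σ = radius/2, radius drawn
  uniformly in 20–24 px. That radius is chosen so that the *thresholded*
  footprint (diameter ≈ 1.1–1.6 radius, depending on the local threshold)
  lands mid-range of the 20–80 px equivalent-diameter acceptance band.
  Marker channels reuse the footprint scaled by the class's marker level;
  the pan-epithelium marker uses a 1.8× wider footprint because it is a
  cytoplasmic/membranous stain — which is also what makes the epithelial
  ring a connected structure a closing radius of 10 px can seal.
* **Classes.** Every cell draws its class from a multinomial over the
  planted proportions — immune 38/40/22% leukocyte/epithelial/stromal with
  24% of leukocytes inside glands and per-compartment T-subset proportions
  (epithelium 1.8/11/9.0%, stroma 5.7/22/8.8% Treg/Th/Te among
  leukocytes); epithelial 54/15/11/20% stromal/basal/benign-luminal/cancer
  with AMACR-positive fractions of 31% (cancer) and 5.3% (benign luminal).
  Class-specific marker levels follow the expression contrasts the
  platform is meant to resolve (e.g. CK18 ≈ 0.200 vs 0.119 normalized in
  cancer vs benign luminal cells; AR elevated in AMACR-negative cancer).
  Site pools are filled gland-by-gland so capacity head-room concentrates
  in the last gland instead of punching holes in every ring; basal-ring
  and lumen sites are rank-interleaved so every benign gland keeps basal
  cells.
* **Modalities.** Fluorescence channels are sampled at 0.64 µm/px over an
  autofluorescence floor (8 gray levels); the brightfield image is
  rendered at 0.88 µm/px through the Beer–Lambert model from haematoxylin
  (all nuclei) and two chromogen concentration maps, under a planted
  similarity transform (default 3° about the slide centre, 1% scale,
  ~30 µm translation). 0.88 µm/px is chosen distinct from the fluorescence
  grid with an integer factor to the 1.76 µm/px working resolution; it
  stands in for scanner-native brightfield resolutions, which would make
  desk-scale fixtures an order of magnitude larger without changing what
  the registration has to solve. Additive Gaussian noise (default SD 2
  gray levels) and 8-bit quantization are applied last; the noise model is
  a convention, not a claim about any particular scanner. Cells are placed
  inside a margin covering the planted displacement, so both modalities
  see every cell.
* **Determinism.** One seed drives everything; identical configurations
  are bit-identical, and the generator restores the caller's RNG state.

What passing the recovery tests does *not* show about real tissue: the
generator has no texture, no uneven illumination beyond what adaptive
thresholding is tested with, no overlapping nuclei in 3D projection, no
staining artefacts, and class-pure marker distributions. It validates the
*computational* chain, not the assay.

# Numerical choices and degenerate inputs

* Otsu ties break toward the lower level; single-valued histograms are
  flagged degenerate and produce empty masks.
* OD is clamped at intensity 1; negative concentrations are clipped and
  logged rather than raised.
* Registration failure (fewer than 3 consensus inliers) raises a distinct
  condition class carrying keypoint/match counts.
* The positivity rule is strict (`>`), so an all-equal marker yields zero
  positives.
* Empty inputs (blank channels, empty masks, zero cell density) return
  empty-but-well-formed results throughout.

# Problem sizes used in the validation suite

The package's own validation runs use: an 8192×8192 px immune-scheme slide
(≈21,000 cells) and a 4096×4096 px epithelial-scheme slide (≈4,300 cells)
for end-to-end recovery, processed with 4096/5120 and 2048/3072 px
core/context tiles and a 1:2 de-convolution downscale (matching the
0.88 µm input to the 1.76 µm working scale); 50 simulated 512 px
registration pairs; 20 random stain matrices × 1000 pixels for the
de-convolution round trip; and exhaustive enumeration for the statistics
oracles. These sizes are the package's choice of a thorough desk-scale
experiment; all parameters scale to full slides unchanged, with the tile
machinery bounding memory.

# Known limitations

* Rigid/affine registration only; no deformable refinement.
* The stain matrix must be supplied for real chromogens; no blind
  stain-vector estimation.
* Segmentation is partition-based; genuinely overlapping nuclei are
  declumped, not modelled.
* The classifiers are hard rule sets; no probabilistic calls.
* The asymptotic KS p-value is inaccurate below ~10 observations per
  group.
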