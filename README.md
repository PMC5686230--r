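# wsicyto — whole-slide multiplexed-IHC tissue cytometry

Multiplexed immunohistochemistry (mIHC) protocols that pair a five-channel
fluorescence acquisition (nuclei + four antibody markers) with a
three-chromogen brightfield acquisition of the *same* tissue section read
out six protein markers per cell across an entire formalin-fixed slide.
`wsicyto` is the image-analysis half of such a platform: it turns the two
raw whole-slide acquisitions into a classified per-cell table and
tissue-cytometry summaries, and ships a synthetic-slide generator with
full ground truth so every stage can be validated by parameter recovery.

The pipeline, in order:

1. **Colour de-convolution** — chromogen absorbances mix linearly in
   optical density (Beer–Lambert): `OD_k = -log10(I_k/255) = Σ_s c_s M_sk`.
   Inverting the stain matrix `M` per pixel recovers haematoxylin and
   two chromogen concentration maps.
2. **Registration** — the brightfield haematoxylin channel (reference) and
   the fluorescence nuclear channel (moving) image the same nuclei, so
   they are aligned with a determinant-of-Hessian blob detector (SURF
   family), upright SURF-style descriptors, ratio-test + mutual matching,
   and a RANSAC affine fit refined by least squares. All channels land on
   a common 0.64 µm/px grid.
3. **Tile–pad–stitch** — cores (default 2048 px) partition the slide
   exactly (half-open intervals); each is processed inside a larger
   centred context window so glands crossing core borders are seen whole;
   objects are kept by the tile whose core contains their centroid, so no
   cell is lost or double-counted.
4. **Segmentation** — glands: Otsu threshold (global or adaptive) on the
   pan-epithelium channel, morphological closing, hole filling (lumina
   count as gland interior), distance-transform watershed for touching
   glands. Nuclei: adaptive Otsu, seeded declumping from smoothed
   intensity peaks, 20–80 px equivalent-diameter filter.
5. **Cytometry** — per-nucleus mean marker intensity (0–255, normalized
   /255); positivity at strictly above mean + k·SD over all cells (k = 1;
   Ki67 k = 3); compartment by centroid containment in the gland mask;
   mask-overlap calls (CD45, CK5+p63) at ≥10% nucleus area.
6. **Classification** — immune scheme: CD45⁺ cells become epithelial or
   stromal leukocytes, sub-typed Treg (CD4⁺FoxP3⁺CD8⁻), Th
   (CD4⁺FoxP3⁻CD8⁻), Te (CD8⁺CD4⁻FoxP3⁻). Epithelial scheme: a gland is
   malignant iff it contains *no* CK5⁺p63⁺ basal cell; its nuclei are then
   cancer cells, benign-gland nuclei are basal or benign luminal, the rest
   stromal.
7. **Statistics** — Fisher's exact test (two-tailed, probability-mass
   rule), two-sample Kolmogorov–Smirnov, Pearson correlation, plus the
   imaging QC metrics S/B = (mean signal − mean background)/mean
   background and heat-retention ratios.

## Worked example

```r
library(wsicyto)

## a synthetic immune-panel slide with known ground truth
cfg <- slide_sim_config(scheme = "immune", image_height_px = 1536L,
                        image_width_px = 1536L, cell_density = 800,
                        rng_seed = 3L)
sl  <- generate_slide(cfg)
run <- run_panel(sl$fl, sl$bf, cfg$bf_resolution, cfg$stain_matrix,
                 panel_config("immune"),
                 run_config(core_size = 1024L, context_size = 1536L,
                            deconv_downscale = 2L))
v <- validate_against_truth(run$cells, sl$truth, match_radius_um = 8)
cat(sprintf("recall %.3f  precision %.3f  class agreement %.3f\n",
            v$recall, v$precision, v$class_agreement))
#> recall 0.967  precision 0.979  class agreement 0.960
run$summary$leukocytes
#>     n pct_of_cells pct_epithelial pct_stromal
#> 1 190     37.03704       20.52632    79.47368
```

`generate_slide()` planted 519 cells at 38/40/22% leukocyte / epithelial /
stromal proportions; the pipeline re-detected 513 of them, matched 97% to
their planted positions and classified 96% of the matched cells
identically. At this small fixture size the subgroup percentages carry
visible sampling noise (190 leukocytes); on whole-slide-scale input
(8192 × 8192 px, ~18,000 cells) the recovered class proportions stay
within ±3 percentage points of the planted values.

For real data, `run_panel()` also accepts a named vector of per-channel
TIFF paths plus a brightfield TIFF (channels are then streamed one at a
time, keeping gigapixel slides memory-bounded), and a thin command-line
tool is installed at `exec/wsicyto`:

```sh
wsicyto simulate --scheme immune --size 2048 --seed 1 --out slide/
wsicyto run --dir slide/ --scheme immune --out run/ --tile-size 2048
wsicyto validate --cells run/cells.csv --truth slide/
```

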