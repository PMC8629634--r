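# cytoseg

Segmentation of cervical cells in cytology images, including the hard
case: **overlapping cytoplasm**. In Pap-stained material nuclei stain
darkest, cytoplasm is intermediate and the background is brightest;
cytoseg turns a grayscale (or RGB) cytology image into per-cell
cytoplasm and nucleus masks, where different cells' cytoplasm masks may
legitimately share pixels.

The package is aimed at image-analysis researchers who need a complete,
dependency-light, fully testable reference stack: every stage is exposed
as its own function, every stochastic step is seeded, and a synthetic
phantom generator supplies exact ground truth so the whole pipeline can
be validated without any external dataset.

## What is inside

**Classical segmentation.** Gray-threshold segmentation
(`binary_threshold`, `multilevel_threshold`), automatic threshold
selection by maximum between-class variance (`max_variance_threshold`):
with the histogram split at `t` into classes with probabilities
θ₁, θ₂ and means μ₁, μ₂ (global mean μ = θ₁μ₁ + θ₂μ₂), the selected
threshold maximizes

    σ_B²(t) = θ₁(μ₁ − μ)² + θ₂(μ₂ − μ)² = θ₁θ₂(μ₁ − μ₂)²

Edge extraction with the gradient, Roberts, Sobel, Laplacian and Kirsch
operators (`edge_magnitude`, `edge_mask`).

**Single-cell clustering segmentation** (`segment_cell`): four methods —
pixel K-means, pixel spatial K-means, superpixel EM (diagonal Gaussian
mixture), and the improved superpixel K-means++ model (superpixel
features + spatial augmentation + D² seeding) — all clustering into
k = 3 tissue classes mapped to nucleus/cytoplasm/background by
ascending mean gray. Includes a SLIC-style superpixel oversegmentation
(`superpixels`) and standalone `fit_kmeans` / `fit_em_gmm` /
`kmeans_pp_init` with per-iteration objective traces.

**Overlapping multicell pipeline** (`segment_overlapping`): graph-cut
clump/background separation (Boykov–Jolly energy, min-cut via max-flow),
nucleus detection inside each clump, Voronoi coarse division seeded at
nucleus centroids, absorbance-evidence overlap compensation, and a merge
into complete cells — one `cell_instance` per detected nucleus.

**Evaluation** (`evaluate_scene`, `evaluate_dataset`): the overlap
challenge metrics — Zijdenbos similarity index
ZSI = 2|A∩B|/(|A|+|B|) with greedy cell matching, object-based false
negative rate FNo (fraction of true cells with ZSI ≤ 0.7), pixel-based
TPp/FPp — plus a Table-style per-method report (`method_table`).

**Phantoms** (`phantom_spec`, `generate_scene`, `generate_dataset`):
seeded synthetic Herlev-style single-cell and ISBI-style overlapping
multicell scenes with exact per-cell ground truth, rendered under an
additive absorbance model so overlap regions are visibly darker.

## Worked example

```r
library(cytoseg)

spec  <- phantom_spec(image_size = c(512, 512), n_cells = 3,
                      overlap_fraction = 0.2, seed = 4)
scene <- generate_scene(spec)
scene$realized_overlap
#> [1] 0.16

pred <- segment_overlapping(scene$image)
pred
#> <scene_segmentation> 4 cells, 512 x 512

report <- evaluate_scene(pred, scene$truth)
report
#> <eval_report> 3 true / 4 predicted cells
#>   ZSI 0.948 +/- 0.024  FNo 0.000  TPp 1.000  FPp 0.000
round(report$per_cell_zsi, 3)
#> [1] 0.921 0.960 0.963
```

The scene has three partially overlapping cells (mean pairwise overlap
0.16 of the smaller cytoplasm). The pipeline detected four nuclei (one
spurious detection inside an overlap shadow) but every true cell was
recovered with cytoplasm ZSI well above the 0.7 "good segmentation"
threshold: mean 0.948, no object-level false negatives, and pixel rates
of TPp = 1.000 / FPp = 0.000 against the ground-truth foreground.

A command-line interface wraps the same pipelines
(`inst/cli/cytoseg`):

```sh
cytoseg synth           --n-images 5 --n-cells 3 --overlap 0.2 --size 512 --seed 0 --out data/
cytoseg segment-overlap --image data/scene_001.png --out pred/scene_001
cytoseg evaluate        --pred pred/ --truth data/ --report report.csv
```

Every run writes a `run-manifest.json` (parameters + seed + version)
beside its outputs, and identical seeded invocations are byte-identical.

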