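---
title: "Segmenting overlapping cervical cells: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting overlapping cervical cells: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoseg)
```

## The problem

In Pap-stained cervical cytology, nuclei stain darkest, cytoplasm is
intermediate, and the slide background is brightest. Automated analysis
needs each cell's cytoplasm and nucleus as separate masks, and the hard
case is the *clump*: several cells whose cytoplasm overlaps, so a pixel
can legitimately belong to more than one cell. cytoseg implements two
segmentation tracks — clustering-based segmentation for single-cell
images and a combined graph-cut/Voronoi pipeline for overlapping
multicell scenes — together with the evaluation metrics used by the
overlapping-cervical-cell segmentation challenges and a phantom
generator that provides exact ground truth.

## Gray-level thresholding

A fixed threshold $T$ produces the binary map $f_T(x,y) = 1$ when
$f(x,y) \ge T$ and $0$ otherwise (`binary_threshold`); the multiband
form assigns mark $g_0$ when $f \le T_0$, $g_k$ when
$T_{k-1} < f \le T_k$, and $g_n$ when $f > T_{n-1}$
(`multilevel_threshold`). Note the two conventions genuinely disagree at
a boundary value: the binary form sends a pixel equal to $T$ up, the
multiband form sends a pixel equal to $T_0$ down. Both are implemented
exactly as stated and each function documents its own rule.

The automatic threshold (`max_variance_threshold`) maximizes the
between-class variance. Splitting the histogram at $t$ into class 1
($\le t$, probability $\theta_1$, mean $\mu_1$) and class 2 ($> t$,
$\theta_2$, $\mu_2$), the global mean satisfies
$\mu = \theta_1\mu_1 + \theta_2\mu_2$ and the criterion is

$$\sigma_B^2(t) = \theta_1(\mu_1-\mu)^2 + \theta_2(\mu_2-\mu)^2
               = \theta_1\theta_2(\mu_1-\mu_2)^2 .$$

Ties in the argmax are broken toward the smallest $t$, so the result is
deterministic. Both algebraic identities are enforced by tests to
$10^{-9}$, and the maximizer is checked against an exhaustive scan.

## Edge operators

`edge_magnitude` implements the forward-difference gradient, Roberts
cross, Sobel, 4-neighbor Laplacian (kept signed: the sign pattern is
what distinguishes a step from a pulse), and the eight-kernel Kirsch
compass maximum. Convolution borders are handled by edge reflection so a
constant image has identically zero response under every operator.
`edge_mask` binarizes a response (strictly above threshold, so threshold
0 keeps exactly the nonzero responses) and can morphologically close
1-pixel gaps so that the boundary of a simple convex object becomes a
closed 8-connected curve.

## Clustering segmentation of single cells

Four variants share one skeleton — cluster image units into $k = 3$
tissue classes, map classes to nucleus/cytoplasm/background by ascending
mean gray value — and differ in unit and algorithm:

| method | units | features | algorithm |
|---|---|---|---|
| `pixel-kmeans` | pixels | gray | Lloyd K-means, mode init |
| `pixel-spatial-kmeans` | pixels | gray + $w_s\,$(row, col) | Lloyd K-means, mode init |
| `superpixel-em` | superpixels | mean gray | diagonal-covariance EM |
| `superpixel-kmeans-pp` | superpixels | mean gray + $w_s\,$(row, col) | K-means, best of 10 K-means++ seedings |

$k = 3$ reflects the three tissue classes of stained cervical material.
The darkest cluster is the nucleus class and the brightest the
background; the cell footprint is the largest connected non-background
component, hole-filled, and the nucleus is the largest darkest-class
component inside it.

Design choices that were genuinely open:

* **Superpixels.** No installed R package provides superpixel
  oversegmentation, so `superpixels` implements a SLIC-style local
  K-means in joint intensity–position space with a compactness
  parameter, deterministic grid initialization, and explicit
  connectivity enforcement. Any tiling with comparable boundary
  adherence would serve.
* **Spatial weight.** Coordinates are normalized to $[0,1]$ and scaled
  by $w_s$. With intensity also in $[0,1]$, a large $w_s$ lets position
  dominate and the three clusters split the image spatially rather than
  by tissue; a sweep on single-cell phantoms showed mean cytoplasm ZSI
  of about 0.45 at $w_s = 0.5$ versus 0.90 at $w_s = 0.1$. The default
  is therefore $w_s = 0.1$, exposed as a parameter.
* **Initialization.** Random pixel sampling almost never lands a center
  in the nucleus (about 1–2% of pixels), leaving Lloyd in a local
  minimum that splits the background instead. The pixel variants
  therefore use `mode_init`: the $k$ most prominent maxima of the
  Gaussian-smoothed gray histogram become intensity centers, with any
  spatial feature initialized from the pixels near each mode. This is
  deterministic and keeps the methods distinct: D² (K-means++) seeding
  remains the signature of the improved superpixel variant.
* **Empty clusters** in Lloyd iterations are re-seeded at the point
  farthest from its assigned center, which cannot increase the
  objective; the per-iteration objective trace is recorded and tested
  to be non-increasing (non-decreasing log-likelihood for EM, whose
  per-dimension variances are floored at $10^{-6}$).

## The overlapping-cell pipeline

`segment_overlapping` composes five stages, each exposed on its own:

1. **Clump/background separation** (`separate_clumps`). Binary labeling
   by minimum $s$–$t$ cut with the standard energy: unary costs are
   $-\log$ likelihoods under two Gaussian intensity models seeded from
   the automatic-threshold split (cells are the darker class), pairwise
   costs are the contrast-weighted Potts penalty
   $\lambda\exp(-\Delta I^2/2\sigma^2)$ on 4-neighbor pairs
   ($\lambda = 2$, $\sigma = 10$ gray levels by default). With
   $\lambda = 0$ the cut reduces to per-pixel maximum likelihood, which
   the tests verify pixelwise, and on images of a few pixels the cut
   value is verified against exhaustive enumeration of all labelings.
   For large images the cut is solved on a block-averaged grid whose
   longest side is capped (default 128); the labeling is upsampled and
   the boundary band re-labeled per pixel by maximum likelihood, which
   restores pixel-accurate boundaries on high-contrast material at a
   small fraction of the full-resolution solver cost.
2. **Nucleus detection** (`detect_nuclei`). The automatic threshold is
   applied to the clump's own histogram; dark components pass area,
   solidity, and compactness filters. Compactness — blob area over the
   area of its largest inscribed disc, $a/\pi r_{in}^2$ — rejects the
   lens-shaped absorbance shadow of an overlap region, which is dark
   enough to masquerade as a nucleus but much more elongated. A
   component that fails the filters is refined recursively (depth 3):
   because a nucleus is darker than a single-overlap shadow, splitting
   the component at its own automatic threshold and filtering both
   sides recovers nuclei fused with shadows; split-derived blobs must
   clear a higher area floor (`max_area/30`) so that noise fragments of
   a shadow are dropped. Finally, blobs whose centroid falls within
   1.25 equivalent radii of a larger blob are fragments of the same
   nucleus and are deduplicated. Nucleus detection is the pipeline's
   acknowledged weak point: every parameter is in `overlap_config`.
3. **Voronoi coarse division** (`voronoi_partition`). Every clump pixel
   takes the label of the nearest nucleus centroid (Euclidean; ties to
   the lowest seed index). Euclidean rather than geodesic distance is a
   deliberate simplification — it is testable against a trivial oracle
   and adequate for convex-ish cells; geodesic distance within the
   clump would be the natural extension.
4. **Overlap compensation** (`compensate_overlap`). The Voronoi
   division assigns each overlap pixel to one cell, but a truly
   overlapping pixel belongs to every covering cell. Under an
   absorbance imaging model, double-covered pixels are systematically
   darker than single-layer cytoplasm, so pixels at least
   `intensity_margin` (default 30) gray levels below the single-layer
   cytoplasm level (median of the clump's bright threshold class) count
   as overlap evidence; each cell annexes the evidence pixels connected
   to its coarse region within `max_extension` of its nucleus centroid.
   Growth is exactly empty at `max_extension = 0` and monotone in it.
   With no overlap there is no evidence and compensation is a no-op —
   the rule adds area only where the image supports it.
5. **Merge** (`merge_cells`). Coarse region ∪ extension, morphologically
   closed, hole-filled, reduced to the component containing the
   nucleus. One cell per detected nucleus, always.

A clump in which no nucleus survives the filters emits no cells and a
warning; a blank (single-level) image yields an empty scene.

## Evaluation

`zsi` is the Zijdenbos similarity index $2|A\cap B|/(|A|+|B|)$ (the
Dice form); a per-cell ZSI above 0.7 is the conventional "good"
threshold. `match_cells` pairs predicted with true cells greedily by
descending cytoplasm ZSI without replacement (verified against the
best assignment over all permutations for small scenes); unmatched true
cells score 0. `fno` is the fraction of true cells with ZSI $\le$ 0.7 —
the boundary value counts as an error, and the denominator is the true
cell count (standard false-negative semantics). `pixel_rates` reports
$TP_p = |P\cap T|/|T|$ and $FP_p = |P\cap\bar T|/|\bar T|$ on the
foreground unions. ZSI is always computed on cytoplasm masks; nucleus
agreement is reported separately and never mixed in.

## The phantom generator

`generate_scene` emulates the structure of the public benchmarks this
kind of method is evaluated on: Herlev-style single-cell crops (one
large cell with one nucleus on a near-uniform bright background) and
ISBI-style multicell fields (512×512 scenes of partially overlapping
cells). Cells are rotated ellipses with low-order harmonic boundary
perturbation and a concentric elliptical nucleus (containment is
enforced by construction; zero perturbation gives an exact analytic
ellipse, which a test checks pixel for pixel). Cell placement tunes
the spacing until the realized mean pairwise overlap,
$|A\cap B|/\min(|A|,|B|)$ averaged over pairs, is within 20% relative
of the requested value (exactly disjoint at target 0).

Rendering uses an additive absorbance model: starting from a background
plane with a smooth illumination gradient, every cytoplasm layer
covering a pixel subtracts $(I_{bg} - I_{cyto})$ and every nucleus
additionally subtracts $(I_{cyto} - I_{nuc})$; Gaussian noise is added
and the result clipped to $[0,255]$. Overlap regions are therefore
darker than single cytoplasm — this is what gives the compensation
stage evidence to work with, and without it overlapping cytoplasm would
be unobservable in a scalar image. Defaults (background 220, cytoplasm
150, nucleus 60, noise σ = 8, gradient amplitude 10) are package
conventions chosen to mimic Pap-stain contrast, not measured values.
Cell size defaults scale with the image: single-cell phantoms get
semi-axes of 20–28% of the image side (a Herlev-like crop), multicell
phantoms 11–16%.

What the phantoms do **not** emulate: real staining texture, debris and
inflammatory cells, focal blur, uneven chromatin, and the 1024×1024
extended-depth-of-field reconstructions of real slides. Passing the
phantom benchmark shows the pipeline recovers cells whose contrast
ordering and overlap darkening match the model; it does not certify
performance on real cytology.

## Benchmark scales and expected figures

The package's own benchmark (see `scripts/acceptance.R` and the
acceptance tests) uses problem sizes chosen to keep a desk run
comfortable: 30 multicell scenes (512×512, 3 cells, overlap 0.2) for
the overlap pipeline and 30 single-cell 160×160 phantoms for the four
clustering methods, plus 20-seed sweeps over overlap
$\{0, 0.1, 0.2, 0.4\}$ at 512×512 for the recovery/degradation
property. On these conditions the overlap pipeline averages a per-cell
cytoplasm ZSI of roughly 0.85 (well above the 0.7 "good" bound), all
four clustering methods average above 0.9, recovery on disjoint scenes
is essentially exact, and quality decreases monotonically with the
overlap fraction — heavy overlap (0.4) is the documented failure mode,
mostly through nucleus detection errors inside multi-layer shadows.

## Known limitations

* Nucleus detection drives everything downstream: a missed nucleus
  deletes its cell (count conservation is with respect to *detected*
  nuclei), and at overlap fractions around 0.4 multi-layer shadows
  both hide true nuclei and occasionally pass the filters as false
  ones.
* The Voronoi division uses Euclidean distance between centroids, not
  geodesic distance within the clump.
* The graph-cut downsampling assumes the clump/background boundary is
  recoverable by per-pixel likelihood within a thin band; very low
  contrast would call for the exact solver (`graph_max_dim = Inf`).
* No contour refinement (level sets, shape priors) is attempted on the
  compensated masks; boundaries inherit the coarse stages' geometry.
* Label maps are stored as 16-bit single-channel TIFF, so a map is
  limited to 65535 regions.
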