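---
title: "Quantitative cytoarchitectonic border mapping and CNN filter-activation analysis on synthetic cortical histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cytoarchitectonic border mapping and CNN filter-activation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`cortexmap` implements two complementary analysis engines for
cytoarchitectonic mapping — the grey level index (GLI) profile approach
for statistically testable area borders, and a mutual-information
workflow for interpreting the filter activations of a convolutional
segmentation network — and exercises both end to end on synthetic
cell-body-stained cortical images with known laminar and areal ground
truth.  Real histological sections are deliberately out of scope: every
claim the test suite makes is a claim about recovery of a *known*
ground truth under controlled conditions.

```{r}
library(cortexmap)
report <- run_pipeline(pipeline_config(seed = 1))
report
```

## The synthetic cortical phantom

The generator emulates a curved or flat ribbon of isocortex carrying
two adjacent areas, rendered at 2 µm/px (the resolution of
high-resolution histology patches).  Cell bodies are placed by an
inhomogeneous Poisson point process with a per-layer areal density and
drawn as area-preserving ellipses (aspect ratio uniform in [1, 1.6],
long axis along the local depth direction) at the layer's stain
intensity, dark on a light background; Gaussian pixel noise is added
and the result quantised to 8 bit.

Two presets encode the rank-order relations that distinguish primary
from secondary visual cortex in cell-stained material:

* `"hOc1-like"`: a broad, tripartite layer IV whose sublayer IVc has the
  strictly highest density of all layers (11 000 cells/mm² of section);
  a cell-sparse layer V (2 000/mm², the minimum among II–VI) against a
  dense layer VI; higher overall packing density.
* `"hOc2-like"`: a single, thinner layer IV; pyramidal cells whose mean
  radius grows from 3.6 µm at the top of layer III to 5.5 µm at its
  base; a weaker V/VI contrast; stronger columnarity (0.45 vs 0.15),
  implemented as a vertical stripe modulation of the point-process
  intensity with 50 µm period and relative amplitude equal to the
  columnarity.

The absolute numbers are package choices, fixed once for realism: with
the default 2 000 µm cortical thickness they produce mean GLI values of
≈ 0.17 (hOc1-like) and ≈ 0.14 (hOc2-like) — the range observed in
cell-body-stained isocortex — with a conspicuous IVc band.  During
design we verified that weaker settings make the GLI compress towards
noise (cells are sparse enough that a 20 µm measuring field holds only
one or two somata), which is not what stained cortex looks like.

What the phantom deliberately does **not** emulate: staining and
illumination artefacts, vasculature, glial/neuronal distinction,
realistic Nissl texture, 3D section geometry, or the gradual transition
zones (border tuft / fringe) of real area borders.  Passing tests
therefore demonstrate correctness of the algorithms and their
statistical calibration under Poisson-type sampling noise — not
performance on real histology.

Determinism: every (area, layer) pair draws from its own derived seed
with a prefix-stable candidate stream (the count comes from a single
inverse-CDF uniform), so raising one layer's density extends that
layer's cell set without touching any other layer.  Identical
configurations render bit-identical phantoms.

## The GLI profile approach

1. **Binarization** — cells stain dark, so foreground is every pixel
   *strictly darker* than the threshold; the default threshold is Otsu's
   (the original literature does not print a value), and the value used
   is always recorded.
2. **GLI image** — the volume fraction of cell bodies per 20 × 20 µm
   measuring field: the foreground fraction of each field, with trailing
   partial fields discarded so every field has equal area.
3. **Traverses** — the Laplace equation is solved with value 0 on the
   layer I/II contour and 1 on the grey/white-matter contour; traverses
   are streamlines of the gradient, seeded at equidistant arc-length
   positions on the outer contour.  The solver is red–black SOR on the
   pixel grid (tolerance 1e-4 on the max residual, over-relaxation at
   the classical optimum, mirror conditions on the open lateral edges);
   streamlines use fixed-step RK4 (0.25 px) on the normalised gradient.
   By default the field is solved at the GLI field spacing (20 µm),
   which is the resolution at which profiles are sampled anyway.
4. **Profiles and features** — each traverse yields a profile of 100
   equidistant bilinear samples of the GLI over relative depth
   x ∈ [0, 1].  The profile is treated as a frequency distribution over
   depth and summarised by its mean amplitude plus centroid, standard
   deviation, skewness and kurtosis (raw m₄/m₂², not excess-corrected),
   and the same five statistics of the absolute differential quotient
   (central differences, one-sided at the ends; the absolute value makes
   the derivative trace a valid frequency distribution).  100 depth
   samples is the convention of the quantitative-cytoarchitecture
   literature.
5. **Border detection** — at each position i the b feature vectors to
   the left are compared with the b to the right by the Mahalanobis
   distance D² = (x̄_L − x̄_R)ᵀ S⁻¹ (x̄_L − x̄_R) with S the pooled
   within-block covariance.  Significance uses Hotelling's
   T² = (b/2)·D², converted to F with (p, 2b − p − 1) degrees of
   freedom and Bonferroni-corrected over the tested positions at
   α = 0.05.  This recipe is a documented package default — the
   upstream literature states only that maxima are tested — and is
   printed with every run.

**Multi-window confirmation.**  A border must be the significant global
maximum (±1 position) for at least 80% of the window sizes b ∈
{12, …, 24}.  Because one window has exactly one global maximum, this
rule cannot literally confirm two borders, and ±1 clustering would
confirm the same peak twice; the package therefore applies it
*per segment*: the best-supported cluster is confirmed, then the
flanking sub-sequences are searched recursively (window sizes too large
for a sub-sequence are dropped and the 80% is taken over the remaining
ones).  Well-separated borders are each the global maximum of their own
segment, and adjacent duplicates cannot arise because a confirmed
position leaves no room for a second peak within its own window span.

Ties in a global maximum break toward the lower index and are flagged.
An optional shrinkage parameter blends S toward a scaled identity for
short sequences; it is off by default.

Calibration is checked two ways at the default settings (20 seeds
each): on two-area phantoms the confirmed border must lie within ±2
traverse positions (± 80 µm at the default 40 µm spacing) of the true
border in ≥ 90% of seeds, and on null phantoms (two identical areas)
≥ 90% of seeds must yield *zero* confirmed borders — the Bonferroni/α
machinery is doing real statistical work, not decoration.

## The dual-branch segmentation network

The full-size architecture follows the published geometry exactly:
10 blocks holding 24 unit-bearing layers.  The block arithmetic admits
exactly one split — three contracting blocks per branch (two 3×3
convolutions then 2×2 max-pooling each) and four expanding blocks
(up-convolution plus two convolutions each) — and each of the three
branches carries 864 units (2592 per instance; 5184 activation maps
over the two instances).  The per-layer unit split
((64,64),(128,128),(240,240) contracting; (128),(96),(48),(16) per
expanding layer) is a package default constrained by the 864 totals,
since the per-layer numbers are not printed in text.  Network layers
are numbered 1–6 (high-res contracting), 7–12 (low-res contracting),
13–24 (expanding).  The high-resolution branch sees 2025 px at 2 µm/px
(4.05 mm), the low-resolution branch 1123 px at 16 µm/px (17.97 mm),
co-centred; at the junction the low-res bottom features are resampled
onto the high-res bottom grid by physical position and concatenated.

The engine (convolution, batch normalisation, ReLU, max-pooling,
up-convolution, softmax cross-entropy, Adam) is implemented in base-R
matrix operations and verified against numerical gradients.  Three
numerical choices deserve note:

* *Normalization statistics* are computed from the current input (batch
  size is one patch); running averages are tracked but prediction runs
  patchwise so that inference sees the same statistics regime as
  training.  Conv biases have exactly zero gradient under batch
  normalisation; they are kept for structural fidelity.
* *Up-convolution* is nearest-neighbour upsampling followed by a 3×3
  convolution (the standard checkerboard-free choice); odd sizes are
  reconciled against the skip connection by nearest resampling.
* *Initialisation* is He-scaled Gaussian from the run seed.  Pre-trained
  auxiliary weights are not reproduced; training is from scratch.

**Desk scale.**  Training the full architecture is not meaningful on a
single CPU, so `default_architecture(scale = ...)` scales unit counts
(floor of 6 per layer, so the characteristic-filter criterion below
stays attainable in every layer) and patch edges while keeping the
physical resolutions.  The analyses in the tests use scale = 1/32:
64 px high-res patches, 36 px low-res patches.  Training uses
balanced patches (equal counts centred on area-of-interest, other
cortex, white matter, background), 32 per class, 16 epochs with Adam
at 1e-2 stepping down to 3e-3 for the final epochs, on a
1200 × 800 px phantom — about 2000 steps.  The "easy"
training condition for the end-to-end property is a two-area phantom
with a strong overall density contrast and no pixel noise, which is
what a desk-scale network with a ~100 µm receptive field can plausibly
separate.  The held-out within-cortex Dice for the area class must
reach 0.8; a negative control trained on two *identical* areas must
stay below 0.75 (it can at best label all cortex as the area of
interest, Dice ≈ 0.67).

## Filter-activation analysis

Each unit's post-ReLU output on an analysis window is one filter
activation map (default branches: high-res contracting and expanding;
the unit totals above count all three).  Maps are normalized to
[0, 1] with the smallest strictly positive value as the lower bound
(constant maps are flagged degenerate), resampled by nearest neighbour
to the window resolution, and compared pairwise by mutual information
over a 256 × 256 joint histogram with bin edges i/256 (the displayed
binning rule; the accompanying prose's "255" is read as the fence-post
count), in bits.  MI(x, x) equals the 256-bin entropy, and the matrix
is symmetric and non-negative by construction.

A map is **characteristic** for its network layer when at least 3 of
its 12 highest-MI partners (within the same network instance, ties at
rank 12 broken toward the lower map index and flagged) come from its
own layer.

The expert's visual assignment of characteristic maps to
cytoarchitectonic feature levels is replaced by a quantitative proxy
computed against the phantom's ground truth:

* `score_cell` — absolute Spearman correlation between the locally
  averaged map (Gaussian, σ = 10 µm, matching the smoothing of the
  cell-density reference) and the smoothed cell-body density, over
  cortex pixels: cellular, fine-scale correspondence.
* `score_layer` — the best folded ROC separation (max(AUC, 1−AUC), so
  0.5 is chance and inverted responses count) of the map for one
  cortical layer against the rest of the cortex: laminar
  correspondence.
* `score_area` — the same for the area of interest against the rest of
  the tissue, computed on the map locally averaged at the 20 µm
  measuring-field scale: areal correspondence.  Normalized activations
  are sparse (many exact zeros), so a pixel-level ranking would be
  dominated by ties rather than by regional selectivity; judging
  *local mean activation* matches how superimposed activations are
  actually read.

Two scoring domains are used, following the resolution logic of the
analysis: characteristic maps of the superficial network layers
(1–12) are scored on the near-border analysis window, while
deeper-layer maps — whose resolution is too coarse for a local
read-out — are scored on the whole section
(`analyse_activations()` wires this up).  Scoring deep maps only near
the border would make the areal criterion unreachable by
construction: there the "rest of the tissue" is just the immediately
adjacent cortex.

The largest score wins; the map is assigned first / second / third
level only if the winner exceeds its threshold (0.5 / 0.85 / 0.85).
This proxy is documented as such — it is not claimed to be equivalent
to expert judgement on real histology.

The end-to-end property asserts the qualitative ordering the real
networks show: a trained desk-scale segmenter yields at least one
third-level (area-indicating) characteristic map, and characteristic
maps of the superficial layers (1–6) out-score those of the network's
deepest point on the cellular score.  "Deepest" here means the
bottleneck (layers 13–15, the coarsest maps): deeper layers are the
lower-resolution ones, and the final expanding layers — though numbered
22–24 — return to full resolution and to cell-scale detail through
their skip connections.

## Problem sizes and runtime choices

The default phantom is 1600 × 1200 px (3.2 × 2.4 mm) with a 2 000 µm
cortex, giving 80 traverses at 40 µm spacing and ~90 independent
measuring fields per profile.  Border calibration uses 20 seeds per
condition; the CNN analyses use the desk-scale architecture on
1200 × 800 px phantoms with a 384 px activation window.  These sizes
were chosen so a complete analysis runs in minutes on one CPU core
while keeping every statistical test at its nominal operating point.

## Known limitations

* The Hotelling/Bonferroni recipe is a defensible default, not a claim
  about the original implementation's exact test; α and the window set
  are exposed as parameters.
* Mahalanobis detection assumes within-area stationarity of the feature
  vectors; gradual within-area gradients (which real cortex has) would
  inflate the pooled covariance and cost power.
* The desk-scale network shares the full architecture's topology, not
  its capacity; counts of characteristic or level-assigned maps are not
  comparable to a full-size, fully-trained network — only the
  qualitative superficial-to-deep ordering is asserted.
* MI estimates on 256² histograms carry positive finite-sample bias
  (bounded in the tests by the independent-noise check); all maps are
  compared at a common reference resolution by nearest-neighbour
  resampling, a choice the method leaves open.
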