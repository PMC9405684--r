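---
title: "Methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculomorph)
```

# The problem

Vessel painting labels the entire cortical vasculature with a lipophilic
dye; wide-field fluorescence then shows bright, curvilinear vessels of a
few pixels width on a dark, noisy background. Morphometric comparison of
such images across groups needs a chain of operations — image preparation,
segmentation or tracing, skeletonization, branch measurement, complexity
analysis, group statistics — each of which has conventions that silently
change the numbers. This vignette states every convention this package
uses, why it was chosen, and what the accompanying tests do and do not
establish.

# Image preparation

* **Coordinates.** 0-based, x right, y down, pixel centers at integer
  coordinates. All user-facing interfaces use (x, y); matrices are stored
  `[row = y, col = x]`.
* **Auto-contrast** maps the `p` and `1-p` intensity quantiles to the
  8-bit extremes with clipping, `p = 0.0035` by default (the documented
  default saturation of the Fiji "Auto" button). Constant images pass
  through unchanged.
* **Sharpening** is the fixed 3×3 kernel (center 12, neighbours −1)/4 with
  replicate padding — the classical "sharpen" of ImageJ-family software.
* **Haze reduction.** The acquisition software's proprietary haze filter is
  replaced by a deterministic, standard equivalent: background = grayscale
  opening with a disk of radius `r`, subtracted and clipped at zero.
  Structures narrower than the disk survive; smooth glow does not. The
  disk radius is the one tunable (px); it must exceed the widest vessel to
  be preserved.
* **Binarization** thresholds at `t` with foreground `>= t`; Otsu's `t`
  maximizes between-class variance over all 256 levels (ties: lowest
  maximizer, making runs reproducible). A constant image has no Otsu
  threshold: the result is an empty mask plus a warning, not an error, so
  batch runs continue.
* **16-bit input** is linearly rescaled to 8-bit before preparation,
  matching the practice of saving prepared images as 8-bit grayscale.
* **Gaussian blur** uses a separable kernel truncated at 4σ (σ in px),
  replicate padding.
* The brightness lower bound that an operator might raise per image to
  suppress background is modelled as the single configurable threshold of
  `binarize(..., "fixed")`; per-image manual tuning is deliberately not
  modelled.

# Vessel segmentation and network metrics

AngioTool-class tools enhance tubular structures before thresholding; the
exact algorithm is unpublished, so the package adopts the standard
equivalent: **Frangi-type multiscale vesselness**. At scale σ the
Hessian (of the σ-smoothed image, scale-normalized by σ²) has eigenvalues
|λ₁| ≤ |λ₂|; bright ridges have λ₂ < 0, blobness `R_b = λ₁/λ₂` and
structureness `S = sqrt(λ₁² + λ₂²)` give

V(σ) = exp(−R_b²/2β²) · (1 − exp(−S²/2c²)),  λ₂ < 0,

maximized over scales (β = 0.5; c = half the maximal S per scale). Scales
default to 1, 2, 4 px — the vessel radii of interest at the supported image
scale — and small objects (< 30 px) are removed. These two knobs are
exposed and flagged as *unvalidated* against any particular AngioTool run.

Whole-field metrics over an ROI polygon: vessel density = foreground
px / ROI px × 100; junction count from the skeleton graph (below);
junction density normalized by the **ROI polygon area** in mm² (not the
foreground area); total vessel length = Σ branch lengths; *average vessel
length* = total / branch count, i.e. the mean skeleton-branch length
between graph nodes — stated explicitly because field tools differ here.

# Skeletonization and the branch graph

* **Thinning** removes *simple* pixels (deletion preserves the local
  8-connected foreground / 4-connected background topology) that are not
  endpoints, in four directional subiterations (N, S, W, E border) until
  stable; within a subiteration the border set is frozen and deletions are
  sequential with the simplicity test re-evaluated on the updated image.
  Every deleted pixel is simple at the moment of deletion, so component
  and hole counts are preserved *by construction* — the property the
  acceptance suite checks on 500 random blob masks.
* **Tagging**: endpoint < 2 skeleton 8-neighbours, slab = 2, junction > 2.
  The tags partition the skeleton. Note a hand-countable subtlety: in a
  1-px plus-sign the four pixels adjacent to the crossing each see two
  diagonal neighbours from the other arm, so the junction *cluster* spans
  5 pixels; merged (below) it is exactly one junction.
* **Graph**: vertices are endpoint pixels and maximal 8-connected clusters
  of junction pixels; edges are slab chains walked from vertex to vertex.
  Cycles are kept (`prune_cycles = "none"` — loop pruning is intentionally
  not used, to preserve skeleton structure); an isolated loop becomes one
  self-edge with undefined tortuosity.
* **Junction merging** (`merge_junctions_px`, default 0). Thinning a
  finite-width Y-bifurcation can yield *two* triple points joined by a
  branch shorter than the vessel diameter, because the strokes of two
  children diverging at angle θ stay fused for ≈ w/(2 sin(θ/2)) px —
  below that scale no centerline algorithm can place a single fork.
  Setting `merge_junctions_px` to the vessel-diameter scale contracts such
  sub-resolution internal branches (and drops the micro-loops they leave),
  exactly as dedicated skeleton-analysis libraries do. The default 0
  reproduces raw AnalyzeSkeleton-style tagging.
* **Branch length** is the ImageJ step-sum (orthogonal 1, diagonal √2,
  × µm/px). This convention overestimates straight digital lines by up to
  8.2% at 22.5°; `length_estimator = "corrected"` offers the calibrated
  corner-count estimator (0.980·n_orth + 1.406·n_diag − 0.091·n_corner,
  worst case ≈ 1% on straight lines) when lengths are compared with
  geometric truth.
* **Tortuosity** T = step-sum length / Euclidean distance between the
  branch extremes V1, V2 (slab pixels adjacent to a junction cluster;
  endpoint pixels themselves at tips). Since every step is at least as
  long as its displacement, T ≥ 1 whenever the extremes differ — this
  holds identically, not statistically, and is asserted on > 1000 random
  branches. T is *always* computed from the step convention so that
  straight orthogonal/diagonal branches give exactly 1, regardless of
  which length estimator is reported. `to_junction_centers = TRUE`
  measures branches fork-center to fork-center instead (the convention
  matched against generator polylines).
* **Collaterals**: branches whose pixel path lies ≥ 50% (configurable)
  inside the anastomosis-zone polygon; the report carries count, lengths,
  a length histogram and mean tortuosity. Tortuosity is computed
  uniformly for all branches; the collateral report merely scopes it to
  the zone.

# Fractal complexity

Box counting uses a grid anchored at the origin: N(s) = number of occupied
s×s boxes, D = least-squares slope of log N vs log 1/s. A single fixed
grid origin is the default (offset averaging available via `offsets`),
keeping runs deterministic. Calibration anchors: a straight line (D = 1
exactly for dyadic sizes), a filled square (D = 2), and the Sierpinski
triangle, whose origin-anchored dyadic counts obey N(2^k) = 3^(d−k)
*exactly*, so the fitted slope equals log 3/log 2 to machine precision —
the strict ordering line < Sierpinski < square is therefore structural,
not statistical.

The local fractal dimension (LFD) map evaluates D in sliding windows
(default 128 px window, 64 px stride, ≥ 50 foreground px, dyadic box sizes
2…window/2). These defaults put vessel-image LFDs in the ~1.0–1.5 range
typical of sparse curvilinear patterns; all are configurable, since the
original FracLac-style settings are not published. Histograms default to
0.01-wide bins; whether counts or normalized frequencies are wanted is
explicit (`normalize`), and group averaging uses the normalized form.
Features: skewness (adjusted Fisher–Pearson) and *excess* (Fisher)
kurtosis of the underlying LFD values, peak frequency = modal bin height
(the value at the mode is exposed separately as `lfd_at_peak`), and
max LFD = upper edge of the highest nonzero bin. Single-bin histograms
have undefined moments and are flagged rather than silently zeroed.

# Live-wire tracing

The cost image blends two ingredients with weight γ (default 0.7, Hessian
scale 2 px, matching the published tracing parameters): the rescaled
magnitude of the dominant *negative* Hessian eigenvalue (ridge evidence
for bright vessels; sign flipped for dark) and the normalized intensity,
each mapped so bright/ridge-like pixels are cheap, floored at 10⁻³. The
original plugin's exact cost functional is not public; the direction of
the γ-blend is documented here rather than asserted as identical.

Tracing is Dijkstra on the 8-connected grid with edge weight
½(c_u + c_v)·steplen (steplen √2 diagonal) — symmetric in direction, so
trace(a→b) and trace(b→a) have equal cost. Neighbour expansion order
(E, NE, N, NW, W, SW, S, SE) and index-based tie-breaks make paths
bit-reproducible. The search window (default 2500×2500) is centered
between the endpoints. Snapping returns the lowest-cost pixel in a 9×9
window, candidates ordered by distance from the click so ties resolve to
the nearest (a uniform window returns the click). Interactive clicking is
replaced by per-branch ordered anchor lists (JSON), for batch
reproducibility. Refinement smooths with a ±5-vertex moving average
(window shrunk symmetrically near the ends, endpoints fixed), keeps every
5th vertex plus both endpoints, and re-rasterizes with Bresenham;
rasterization paints width-3 strokes via Chebyshev dilation (a width-3
horizontal stroke is exactly 3 px tall).

# Synthetic data: what it emulates, what it does not

`generate_tree()` renders a recursive bifurcating tree as anti-aliased
strokes (ground-truth mask = anti-aliased intensity ≥ 50%, fixing
rasterization ambiguity) over a constant background with additive Gaussian
noise. Defaults are chosen once, from the imaging context the package
targets, and then frozen:

* root length 160 px decaying by 0.9 per level at 1 µm/px — branch lengths
  ~105–160 µm, the range where most traced artery branches fall;
* bifurcation angle 90° at the root, shrinking by 0.8 per level: distal
  arterial bifurcations are narrower than proximal ones, and this schedule
  additionally guarantees a planar embedding to depth 4 (~22 px clearance
  between non-adjacent branches). An earlier constant-angle draft made
  depth-4 cousins cross, which would silently invalidate the generator's
  own counts — the generator now *warns* when branch chords approach
  within stroke-touching distance or diverge too shallowly;
* stroke width 3 px, background 10, jitter/curvature/noise zero by
  default, so the default object is exactly its analytic description;
* noise is additive Gaussian, not Poisson: 8-bit projections of the kind
  emulated are background-dominated; a Poisson option is future work;
* sinusoidal curvature (vanishing at branch ends) gives closed-form
  ground-truth tortuosity = polyline arc length / chord.

What a green recovery test establishes: on clean, planar, width-3 trees
the full pipeline (rasterize → thin → graph with diameter-scale junction
merging) reproduces branch/junction/endpoint counts exactly and branch
lengths within 5% (fork-to-fork, corrected estimator). What it does not
establish: performance on crossing vessels (2-D projections of 3-D
networks *do* cross), on width variation, uneven staining, or real noise
statistics — those remain the user's validation burden on real data.

`generate_grid()` provides the anastomotic-network stand-in (n_h·n_v
crossings, analytic branch counts); `generate_fractal_fixture()` the
box-counting anchors; `add_imaging_noise()` calibrated noise
(sd of the added noise verified within 5%).

# Statistics

One-way ANOVA and Tukey HSD are computed from explicit sums of squares and
the studentized range distribution; the test suite cross-validates both
against `stats::aov`/`TukeyHSD` to 10⁻⁶ on random datasets — the package
computation and the reference implementation stay two independent routes.
The two-way (age × sex) ANOVA uses **Type II** sums of squares by default
(`SS(A|B)`, `SS(B|A)`, `SS(AB|A,B)` via nested model comparisons): group
sizes in the emulated designs differ mildly and the interaction is
secondary, the textbook case for Type II; Type III (sum-to-zero
contrasts) is one flag away since the original analysis software does not
state its choice. The post hoc family is the male-vs-female contrast
within each age bin — m = number of age levels tests — with Šidák
adjustment `1 − (1 − p)^m` on t statistics that use the full-model MSE.
Normality tests (Shapiro–Wilk, D'Agostino–Pearson omnibus) are advisory
outputs only and never gate the ANOVA. Covariance ellipses come from the
eigen-decomposition of the 2×2 sample covariance (semi-axes k·√λ,
orientation of the principal axis in [−90°, 90°), covariance sign
reported); k defaults to 2 and is purely a display multiplier.

Calibration facts the acceptance suite verifies rather than assumes:
F = t² for two groups; empirical type-I error 5% ± 2% under the global
null (2000 simulations); an injected 2σ sex effect at one age detected by
its Šidák comparison in ≥ 90% of 100 seeded runs.

# Pipeline and reproducibility

`run_pipeline()` drives simulate/load → prepare → segment → thin → graph →
metrics → fractal from one YAML/JSON config, writing every intermediate
(TIFFs, CSVs) and a manifest (package version, config, seed, md5 of every
output). Intermediates are always written so each stage is independently
auditable. No timestamps enter any output, all randomness flows through
the config seed via a private RNG scope, and rasterization/thinning/
Dijkstra are deterministic — identical configs therefore reproduce
bit-identical files, which the acceptance suite asserts on checksums.

# Known limitations

* 2-D only: inputs are projections; 3-D voxel skeletonization and 3-D
  tracing are out of scope, and projection-induced vessel crossings are
  quantified as junctions, as in the emulated workflow.
* No vessel diameter estimation, lacunarity, or multifractal spectra.
* The TIFF codec is deliberately minimal (uncompressed baseline grayscale);
  PNG and compressed TIFF are not read — convert upstream. (No image-codec
  library is assumed at run time.)
* Thinning's directional sweeps are not exactly rotation-equivariant:
  90°-rotated masks give identical counts but branch lengths may differ by
  a fraction of a percent.
* Frangi scales/thresholds are not validated against any particular
  AngioTool configuration; treat absolute densities as convention-bound,
  comparisons within a convention as meaningful.
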