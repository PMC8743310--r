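---
title: "Methods: segment-resolved expression atlases with segatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment-resolved expression atlases with segatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segatlas)
```

# The data model

`segatlas` operates on organs that have been physically dissected into a
fixed set of anatomical segments, each profiled by bulk RNA-seq. The atlas
resolution is therefore the segment — typically 18 pieces for an adult
mouse heart — not the cell or the voxel. Two objects carry a dataset:

* a `SegmentExperiment` (a `SummarizedExperiment` with one `log2cpm`
  assay): genes × segments, finite log2 CPM values, unique gene and
  segment IDs, with segment order fixed by the dataset header;
* a `SegmentedModel`: one named triangle mesh per segment, all in one
  right-handed y-up frame, ordered by first appearance in the OBJ file.

The two are linked only by their segment IDs. Every color application
re-checks that the ID sets match; a dataset whose column count differs
from the model's segmentation is rejected at load time
(`expectedSegments`), because a matrix that cannot be mapped
piece-for-piece onto the model is not interpretable in this design.

# Normalization

Raw counts are converted by the plain log2 CPM transform
$v_{gs} = \log_2(c_{gs}/L_s \times 10^6 + p)$ with library size
$L_s = \sum_g c_{gs}$ and prior pseudo-count $p = 1$ by default, so zero
counts map to 0 and columns are invariant under uniform scaling of a
library. We deliberately implement no between-sample scaling-factor
normalization (TMM and relatives): the atlas consumes matrices that are
already normalized upstream, and the built-in transform exists so raw
matrices can be brought onto the same scale with the most common
convention. The prior is exposed as a parameter because conventions
differ; $p = 1$ keeps all-zero genes at exactly 0 in every segment.

# View modes and color mapping

Two scalings bring a gene's values to $[0,1]$ before coloring:

* **normalized** — per-gene min–max across segments. This is the pattern
  view: every gene uses the full color range, so spatial shape is
  comparable across genes while magnitude is discarded. A zero-variance
  gene has no pattern; it is mapped to 0.5 (palette midpoint) with a
  warning rather than erroring, so flat housekeeping genes still render.
* **absolute** — scaling against the dataset-wide min/max of the loaded
  matrix, clamped to $[0,1]$. This preserves cross-gene magnitude
  differences. Nothing in the interchange formats pins down what an
  "absolute" scale should be relative to; we chose the dataset-global
  range, recomputed per loaded dataset, as the only choice that needs no
  extra state. It is a package design decision, and it means absolute
  colors are comparable within one dataset but not across datasets.

Colors are linear interpolations in RGB space between two endpoints:
blue (0,0,255) → red (255,0,0) by default, blue → yellow for the
color-vision-deficiency palette. RGB-space interpolation is the minimal
reading of a "linear color gradient" (the default palette passes through
purple at mid-scale); the palette object isolates this choice so
perceptually uniform spaces could be added without touching callers.
Channels are rounded half away from zero, making the midpoint
reproducible bit-exactly: `interpolateColor(0.5)` is (128, 0, 128).

# The similarity statistic

The ranking statistic is the absolute Pearson correlation of per-segment
profiles, reported as a percentage:
$\mathrm{sim}(x, y) = 100\,|r_{xy}|$. Consequences worth stating
prominently:

* it is invariant under affine maps of either profile, so "same spatial
  pattern at different magnitude" scores 100;
* anti-correlated genes also score 100 — the ranking finds shared
  pattern, not shared direction;
* it is undefined for constant profiles. Constant genes are *skipped and
  reported* (`skippedGenes()`), never silently scored 0: an undefined
  correlation should be visible.

Ties are broken by lexicographic gene ID so output is a deterministic
total order. With 18 segments a correlation has 16 degrees of freedom;
we attach no p-values, because the atlas is an exploratory ranking tool
and printed significance on ~75,000 ranked transcripts would be
misleading without careful multiplicity treatment, which is out of scope.

The group contrast scores each gene, restricted to the selected segments,
against the binary template (1 on region A, 0 on region B) with the same
statistic. Restricting to the selection — rather than weighting all
segments — follows from the semantics of "match this grouping
specifically": segments outside the selection carry no information about
the contrast. A secondary `mean_diff` method (absolute difference of
group means after per-gene min–max scaling over the selection) is
available where a magnitude-of-separation reading is wanted; correlation
remains the default and the documented statistic.

The heatmap comparison maps $|v_A(s) - v_B(s)|$ per segment (raw values
in absolute view, per-gene min–max values in normalized view) and colors
the diff vector by its own min–max, so "most different" is always exactly
the high color within one comparison. The scaling is per-comparison, not
global: the map answers "where do these two genes differ most", not "how
large is the difference in absolute units" (the exported table carries
the raw diffs for that).

# Geometry and rendering

Rigid whole-model transforms take a rotation matrix (validated orthogonal
with determinant +1 within 1e-9) plus a translation, applied jointly to
all segments; pairwise vertex distances are preserved to well below 1e-9.
The exploded ("expanded") layout translates segment $i$ by
$(i-1)\cdot\mathrm{spacing}$ along one axis in canonical order; the
default spacing of 1.2× the mean segment extent along that axis leaves a
visible gap between neighbours. Exploding along the opposite axis with
the same spacing restores coordinates exactly, since only translations
are involved.

Snapshots are rendered by a small deterministic software rasterizer
(perspective camera, z-buffer, flat per-segment shading, white
background) rather than a GPU pipeline, so identical inputs give
pixel-identical PNGs on any machine. The camera orbits the model centroid
at elevation 0 with a 60° vertical field of view, framing the bounding
sphere with a 10% margin, at `nAngles` equally spaced yaw angles starting
at 0; no convention fixes which four angles a "four-view" capture should
use, so equal 90° spacing at eye level was adopted as the symmetric
choice. Flat shading (no lighting) keeps every rendered pixel exactly at
its segment's mapped color.

Mesh interchange: OBJ in (one named `o`/`g` block per segment; vertices
belong to their block, faces must reference them), binary little-endian
PLY with per-vertex uchar RGB and OBJ+MTL (one material per segment) out.
These small readers/writers are part of the package because its mesh
dialect — named segment blocks with per-segment uniform vertex colors —
is the contract under test, down to bit-exact color round trips.

# The synthetic-data generator

The generator emulates the *shape* of a dissected-organ atlas dataset —
genes × 18 segments on the log2 CPM scale, a handful of spatially
structured genes over an unstructured background — at desk scale
(default 500 genes standing in for a ~75,000-transcript matrix; all
tests and the acceptance script use 40–500 genes, sizes chosen so the
whole suite runs in about a minute). Planted patterns:

* `uniform` — flat at `baseline` (default 4, a moderate log2 CPM level);
* `marker(segments)` — `baseline + amplitude` on the listed segments.
  The default amplitude 5 (≈32-fold) models a strong regional marker;
* `gradient` — linear ramp of span `amplitude` along canonical order;
* `copy_of(gene, scale, offset)` — affine image of another planted
  gene's noiseless pattern, the ground truth for synexpression retrieval;
* `group_template(A, B)` — high on region A, baseline elsewhere.

Planted genes receive i.i.d. Gaussian cell noise $N(0,\sigma^2)$
(default $\sigma = 0.5$); background genes are i.i.d. $N(4, 1)$.
Gaussian-on-log is the standard minimal noise model at this scale; the
generator makes no attempt at count-level (negative binomial)
realism, library-size artefacts, batch effects, or the gene–gene
correlation structure of real transcriptomes. Passing retrieval tests on
these fixtures therefore demonstrates the correctness of the ranking
machinery, not its behaviour under real biological covariance. RNG is
Mersenne-Twister with inversion normal sampling, fixed explicitly so
seeds are portable.

Under the default study conditions — 18 segments, 500 genes, a
half-organ marker of amplitude 5 copied once, noise sd 1 — the planted
copy is the top-ranked gene in ≈99% of seeded replicates; at noise 0
retrieval is exact (100.0, rank 1). A shallow pattern (e.g. a gradient
spanning only 5 log2 units with noise on both copies) would not clear
that bar: recovery is a property of signal-to-noise, and the marker
amplitude was fixed at design time as the realistic "strong regional
gene" case.

# Numerical choices and degenerate inputs

* Scores are clamped at 100: floating-point correlation of an exact
  affine copy can land one ulp above 1.
* Zero-variance vectors: error (`zeroVariance`) in `similarityScore`;
  skipped-and-reported in rankings; mid-scale 0.5 in display scaling.
* An all-equal diff vector in the heatmap (including gene-vs-itself)
  colors all segments at the palette midpoint — the min–max rule's
  degenerate case, shared with flat-gene rendering.
* CSV values are written with 6 significant digits; one write/load cycle
  is lossy at most in the 6th digit, after which the cycle is
  bit-stable (idempotent).
* Session-log timestamps are UTC ISO-8601 with milliseconds and must be
  non-decreasing; lexicographic comparison then equals chronological
  comparison.
* PLY coordinates are float32 (≈7 significant digits) by format
  convention; colors are 8-bit and round-trip bit-exactly.

# Known limitations

Whole segments are the color unit — no within-segment gradients, matching
the per-piece dissection resolution. The absolute view's dataset-global
range makes cross-dataset color comparison meaningless. The similarity
statistic conflates correlated and anti-correlated patterns by design;
users who need the direction should inspect the sign of the underlying
profiles. The renderer is a flat-shaded preview tool, not a
publication-quality raytracer. Only the OBJ dialect described above is
read; other segmented-mesh conventions (shared vertices across segments,
FBX/DAE containers) are out of scope.
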