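---
title: "Quantifying enteric neurons with enteroquant: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enteric neurons with enteroquant: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enteroquant)
```

## The problem

The enteric nervous system is imaged as flat two-dimensional wholemount
preparations in which neuronal somata, labeled with the pan-neuronal
marker Hu, cluster into ganglia. Routine quantification asks for (i) the
total neuron count, (ii) the proportion of neurons expressing
neurochemical markers such as nNOS, calbindin (Calb) or calretinin
(Calret), (iii) ganglion-level statistics (count, cells per ganglion,
neurons per mm^2 of ganglionic area), and (iv) an account of the spatial
distribution of neurons that is robust to how strongly the tissue was
stretched during preparation. `enteroquant` implements this
quantification pipeline as a scriptable library: calibrated image and
label I/O (including ImageJ ROI archives for importing segmentations
from other tools), pixel-size normalization, a classical baseline
segmenter, ganglia delineation, marker calling, proximal-neighbor
spatial statistics, and the instance-segmentation evaluation metrics
used to benchmark such pipelines.

## Pixel-size normalization

Cell detectors are calibrated at a fixed physical resolution. Images are
resampled so that one pixel corresponds to 0.568 um for mouse and rat
tissue and 0.9 um for human tissue (larger somata); at those targets the
mean soma covers about 701.2 px^2. The resampling factor is
`pixel_size_um / target`; output dimensions round half away from zero.
Intensities are interpolated bilinearly; label maps travel back to the
native grid by nearest-neighbor resampling, which cannot mix label
identities. The interpolation scheme for intensities is a design choice
(any smooth interpolant would do); bilinear was chosen as the cheapest
scheme without overshoot.

## Baseline segmentation

The deep-learning cell models that motivate this pipeline are not
re-implemented here; any external segmentation can be imported as a
label TIFF or an ImageJ ROI archive and flows through the identical
downstream analysis. For self-contained operation the package provides a
classical baseline for round, star-convex somata:

1. percentile normalization to `[0, 1]` (`pmin = 1`, `pmax = 99.8`);
   a constant channel normalizes to zeros with a warning;
2. multi-scale Laplacian-of-Gaussian blob detection (scales 3-8 um,
   responding maximally near `radius / sqrt(2)`), local maxima with
   response at least `score_threshold = 0.06` and pairwise separation at
   least 6 um become seeds;
3. marker-controlled watershed (priority flooding, 4-connected) over the
   inverted smoothed intensity, restricted to the foreground mask
   (smoothed normalized intensity at least `fg_threshold = 0.3`);
4. area filtering to 40-1200 um^2 and per-label morphological opening by
   0.6 um to smooth boundaries.

The foreground default of 0.3 sits well above the normalized background
level of a typical fluorescence field (percentile normalization places
the background of a signal-bearing image near 0.1-0.15) while staying
under the dimmest somata of interest (about 0.5 after normalization).
All steps are deterministic; ties in the flooding order are broken by
insertion order, so identical inputs give identical label maps.
Overlapping somata are not modelled: watershed partitions are disjoint,
which is the documented divergence from detectors that resolve
overlapping star-convex shapes.

## Ganglia delineation

When no second marker outlines the ganglia, the neuronal outlines are
expanded by a user-specified distance and the expanded union is split
into 8-connected components. The expansion is computed by thresholding
an exact Euclidean distance transform, not by iterating structuring
elements, so there are no connectivity artifacts. Two cells merge
exactly when their edge-to-edge gap is below twice the expansion radius
(at exactly twice the radius the expanded outlines are tangent and count
as one component). The default radius is data-adaptive: half the mean
cell equivalent diameter, which realizes the demarcation convention that
two ganglionic structures are separate when the gap between them exceeds
one cell diameter. Externally produced ganglia probability maps are
binarized at a user threshold (default 0.8, inclusive) with a minimum
component area. Cells are assigned to the ganglion with maximal pixel
overlap, ties toward the lowest ganglion id; the alternative rule
(centroid containment) differs only for cells straddling a boundary and
max-overlap degrades more gracefully for lobulated ganglia.

Because cell counts per ganglion are heavily right-skewed (one giant
ganglion inflates a mean), summaries report both mean and median cells
per ganglion; density is assigned cells per mm^2 of total ganglionic
area.

## Marker positivity

The matching rule between the pan-neuronal segmentation and a subtype
segmentation is the central open design decision of this module, and it
is surfaced as configuration rather than hidden. With a subtype
segmentation available, a cell is positive when at least a fraction
`f = 0.5` of its pixels are covered by any subtype label — half-coverage
tolerates boundary disagreement between independently produced
segmentations while rejecting incidental touches. Without one, the cell
mean intensity is compared against `median + k * MAD` (`k = 3`) of the
non-cell pixels, a robust analogue of a three-sigma rule. Combinations
(e.g. Calb+/Calret+ double positives) are element-wise boolean
operations with proportions denominated on the total cell count.

## Proximal-neighbor analysis

Edge-to-edge distance is the physical gap between soma boundaries, not
the centroid distance. On rasters the package defines
`gap = max(0, d_min - 1 px) * pixel_size`, where `d_min` is the minimum
boundary pixel-center distance; 4-adjacent labels therefore touch
(gap 0) and the value tracks the physical edge separation to within half
a pixel. The sparse symmetric distance graph keeps pairs within a search
radius (default four times the threshold) and is computed from per-label
boundary pixels with bounding-box pruning; the test suite verifies exact
agreement with an all-pixel-pairs brute force.

A cell is a proximal neighbor (PN) of another when their gap is at most
the threshold `T` (inclusive). The default `T = 6.5` um derives from the
mean edge-to-edge spacing between neurons inside ganglia, estimated with
a local-thickness transform of the intra-ganglionic space (mean 6.32 um
on the motivating mouse-colon data, rounded up to the next 0.5 um; the
package reproduces this derivation on synthetic scenes, see below).
Because stretch rescales distances only mildly relative to `T` while
cell density falls with the stretched area, PN counts stay stable where
densities do not — the property that makes PN distributions comparable
across differently stretched preparations. The neighbor relation is
purely distance-based, not restricted to same-ganglion pairs, matching
that robustness argument.

Outputs are per-cell counts `k`, raw histograms over `k`, histograms
normalized by total cell count (bins sum to one), a neighbor-count map
(each cell painted with its `k`; background carries the sentinel -1 to
stay distinct from `k = 0`), and cross-type counts (neighbors restricted
to marker-positive cells, centers optionally restricted, denominator the
number of centers).

### Local thickness

The local thickness at a pixel is the diameter of the largest disc fully
inside the mask that covers the pixel. The discrete convention: candidate
disc centers live on the half-integer pixel grid; the admissible radius
at a center is the exact Euclidean distance to the nearest background
pixel *square* (pixels outside the image count as background). This
makes a one-pixel line one pixel thick and a w-pixel bar w pixels thick
(the best centers sit between pixel rows). Implementation is an exact
integer squared-distance transform on the doubled grid followed by disc
painting with conservative domination pruning; radius and coverage
comparisons are integer, so the result equals a brute-force disc search
bit for bit (verified on randomized instances).

`estimate_threshold()` averages local thickness over all pixels of
`ganglia AND NOT cells`. Averaging over all pixels (rather than only
ridge pixels) is a documented choice: it weights each corridor by its
area, which matches how the spacing statistic is used (a typical
inter-soma distance, not a skeleton summary). The suggested threshold is
the mean rounded *up* to the next 0.5 um, mirroring the 6.32 to 6.5
mapping.

## Evaluation metrics

Instance matching computes the IoU matrix over intersecting
ground-truth/prediction pairs and a one-to-one assignment maximizing
total IoU (Hungarian algorithm; greedy matching was rejected for order
dependence). Matches with IoU at least tau are true positives;
`F1 = 2TP / (2TP + FP + FN)`. For threshold sweeps the assignment is
computed once and thresholds applied to it, which makes the F1 curve
non-increasing in tau by construction. The percentage cell count error
is `100 |N_gt - N_pred| / N_gt`, symmetric in the error direction.
Semantic mask quality is plain IoU with the conventions `empty vs empty
= 1`, `empty vs non-empty = 0`. Partition quality over the ground-truth
foreground is scored by the Adapted Rand error (one minus the F-score of
the pair-counting contingency) and the variation-of-information
components in bits, oriented as `voi_split = H(gt | pred)` (a prediction
that merges ground-truth objects has positive `voi_split`) and
`voi_merge = H(pred | gt)`.

## The synthetic scene generator

Every stage is testable without external data because the generator
produces calibrated wholemount-like scenes with complete ground truth.
What it emulates, and the values it is calibrated to:

* **Soma geometry.** Star-convex polygons: 8-16 radial knots on a base
  radius modulated by low-frequency harmonics (modes 2 and 3, amplitudes
  up to 8 % and 5 %). The base radius is drawn from a truncated normal
  with a 14 % coefficient of variation and mean 8.63 um, calibrated so
  that the rendered mean soma area at the default 0.568 um/px is 701.2
  px^2 (the normalized training-set mean area; the calibration absorbs
  the polygon chord shrinkage of the knot representation). The 14 %
  radius CV reproduces the reported ~28 % area CV.
* **Spacing.** Within a ganglion each new soma is anchored to a
  previously placed one at an edge-to-edge gap drawn from a normal with
  mean 6.32 um and s.d. 5.17 um — the empirical inter-neuron spacing
  distribution — truncated to [0.5, 16.66] um. The lower truncation
  avoids fused somata; the upper truncation (mean + 2 s.d.) keeps each
  ganglion one spatial cluster. Placement walks the candidate outward
  until the exact polygon-to-polygon distance equals the draw, and every
  non-anchor soma must clear the candidate by at least that gap, so the
  draw is realized as the nearest-neighbor edge distance. One shape is
  drawn per soma before placement retries; redrawing on failure would
  bias accepted sizes downward in crowded clusters.
* **Ganglia ground truth.** One label per cluster: the cluster's somata
  closed by a disc of half the mean gap (filling the typical inter-soma
  corridors without adding an outer halo) united with a corridor along
  every anchor link. The corridor width is 0.8 times the drawn gap,
  calibrated so that the local-thickness estimate over the
  intra-ganglionic space reproduces the programmed spacing distribution
  (the physical corridor between curved boundaries narrows toward the
  somata, so the equivalent-thickness rectangle is slightly narrower
  than the gap at closest approach). Clusters are placed far enough
  apart that ganglia never interact.
* **Markers and optics.** Independent Bernoulli marker flags per cell
  (defaults: Calret 25 %, Calb 6 %), one rendered channel per marker
  containing only flagged cells, per-cell intensities uniform in
  [0.6, 1], Gaussian blur of 0.8 um, additive Gaussian noise with
  SNR 10 (mean soma intensity over noise s.d.).

A single seed governs every draw; the rendering noise stream is derived
from it, so identical specs give bit-identical scenes and an identity
stretch reproduces the original exactly. `stretch_scene()` scales
positions and outlines before rasterization — the synthetic analogue of
imaging the same field under stretch: counts and flags are preserved,
areas scale with the stretch product, ganglionic density with its
inverse.

What the generator does *not* emulate: overlapping somata (2D
projections of thick ganglia), uneven illumination and staining
heterogeneity, autofluorescent background structures (interganglionic
fiber tracts), non-Gaussian camera noise, and anisotropic stretch of the
cells themselves (stretch moves cells; it does not deform individual
outlines beyond the affine map). Passing tests on these scenes therefore
validate the analysis machinery and its conventions, not the difficulty
of segmenting adverse real images.

## Numerical choices and degenerate inputs

* Rasters are (row, col), origin top-left, 0-based in the coordinate
  convention; polygon vertices are (x = col, y = row) pixel centers.
  Polygon fill paints pixels whose centers are inside (even-odd,
  half-open boundary rule); overlapping ROIs rasterize later-wins.
* Anisotropic pixel sizes are rejected; areas are always pixel count
  times the squared pixel size.
* Label TIFFs are written as 16-bit unsigned integers (roundtrip
  bit-exact, at most 65535 objects); intensity TIFFs as 32-bit floats
  with resolution tags in pixels per centimetre. ImageJ ROIs are written
  with sub-pixel float coordinates so vertex roundtrips are exact to
  float precision; ovals are imported as 64-vertex ellipse polygons.
* Percentiles use the default quantile definition (type 7).
  Output dimensions under rescaling round half away from zero.
* Empty inputs are defined, not errors: an all-zero label map has zero
  objects, an empty ROI list rasterizes to an all-zero map, an empty
  foreground yields an empty segmentation. Errors are reserved for
  contradictions (no background pixels for an intensity threshold, a
  fully occupied ganglion region, probability values outside [0, 1]).
* Seeded watershed flooding and connected-component labelling order
  their output deterministically (insertion order and column-major first
  pixel respectively).

## Problem sizes in the test suite

Unit tests run on 512 px scenes with two ganglia (about 16 somata);
calibration properties pool 20 default scenes of 1024 px with four
ganglia (about 60 somata each, 1100+ somata pooled); oracle-equivalence
checks use 50 randomized instances up to 64 px against brute-force
references; the tile-sampling experiment uses 3000 uniformly placed
cells on a 13.9 mm^2 field with the three tile areas that emulate 10x,
20x and 40x objectives. These sizes were chosen so the full suite
exercises every code path at statistically meaningful cell counts while
remaining comfortable to run interactively.

## Known limitations

* Strictly 2D: maximum-intensity projection must happen upstream, and
  somata overlapping in projection are not separated.
* The baseline detector assumes round, star-convex somata; cells with
  complex morphology (glia, macrophages, interstitial cells) are out of
  scope.
* The intensity-based marker rule assumes a spatially flat background;
  strong illumination gradients require the overlap rule with an
  external subtype segmentation.
* Ganglia probability maps are thresholded at a user value; no
  per-image threshold optimization is performed.
* Neighborhood-enrichment analysis over a spatial graph and
  colocalization statistics are out of scope.
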