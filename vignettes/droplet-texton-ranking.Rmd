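---
title: "Ranking crystallization droplets by texton texture"
author: "dropRank maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking crystallization droplets by texton texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropRank)
```

## The problem

High-throughput crystallization imaging produces hundreds of droplet
images per plate, and the experimentally decisive events — crystals,
microcrystals, crystalline showers — are rare. Classifying droplets into
discrete outcome classes is notoriously unreliable (human annotators
disagree, and rare-event false negatives are costly), so this package
takes a different route: every droplet receives a continuous score, the
posterior probability of the "interesting" (crystalline) class under a
two-class random forest, and droplets are *ranked* by that score. No
classification threshold is ever chosen; the score only rearranges the
viewing order so that likely crystals are seen first, and the sorted
score vector of a plate serves as a quick profile of the whole
experiment.

## The texture model

Droplet content is described by **textons**: prototype vectors of
filter-bank responses. An image is convolved with a 38-filter bank of
anisotropic Gaussian-derivative kernels — edge (first-derivative) and bar
(second-derivative) filters at six orientations and three scales, plus a
Gaussian and a Laplacian of Gaussian. Per pixel, only the maximum edge
and bar response over the six orientations is kept at each scale, giving
an 8-vector (3 edge + 3 bar + 2 symmetric) that is quasi-invariant to
image rotation. The bank is used at half its canonical scale (25 px
support, derivative sigmas 0.5/1/2, symmetric sigma 5), which suits
precipitation texture at the working resolution of roughly 4.5 µm per
pixel; `makeFilterBank(scaleFactor)` regenerates it deterministically at
any scale.

One choice deserves a note. "Maximum response over orientations" is
ambiguous for signed responses: edge kernels are antisymmetric and their
sign flips at the 180° orientation wrap, so a signed maximum is not
rotation invariant. `applyFilterBank()` therefore records the maximum
*magnitude* for edge channels, and for bar channels the signed value of
the maximum-magnitude response (bar kernels are 180°-symmetric, so the
sign is stable and preserves ridge-versus-valley polarity, which helps
separate bright crystals from dark granules).

A droplet's descriptor is the frequency histogram of nearest-texton
labels (Euclidean distance, ties to the lowest index) over its in-mask
pixels. Histograms are compared with the χ² distance
½ Σ (xᵢ−yᵢ)²/(xᵢ+yᵢ) on unit-normalised bins; `wardCluster()` runs
Ward-linkage hierarchical clustering under this distance as a qualitative
check that the descriptors group similar precipitation patterns.

## Building the dictionary

The dictionary is built in two clustering stages
(`buildDictionary()`):

1. **Per image**, pixel response vectors are clustered with a
   diagonal-covariance Gaussian mixture fitted by variational Bayes
   (`clusterImageTextons()`). The component count is selected by the
   data: the fit starts from a cap of 30 components with a sparse
   Dirichlet prior (concentration 1/K) and components whose posterior
   weight falls below 10⁻³ are pruned. No per-image tuning is needed.
   Initialisation is seeded k-means, making the whole build
   reproducible.
2. **Across images**, the per-image centres are concatenated and
   de-duplicated with DP-means (`dpMeans()`, threshold λ): a centre
   farther than λ from every cluster spawns a new cluster (penalty λ²
   per cluster). Unlike stage 1, which treats isolated points as noise,
   DP-means keeps far-away singletons — a rare texture seen in training
   is a texture worth keeping.

The two stages run separately over a precipitation image set and over
the crystal-related centres of a crystal-containing image set, so
crystal textures cannot be washed out by the far more common
precipitation patterns. "Crystal-related" is operationalised as: at
least half of the centre's supporting pixels fall inside the image's
crystal mask (the synthetic fixtures carry ground-truth masks; with real
images a curated mask or manual selection plays this role). The final
dictionary is ordered with the lowest-magnitude texton first and the
remaining entries sorted by distance to it.

Two size protocols are supported: the fixed-λ protocol (λ = 0.5), and a
calibrated protocol in which λ is bisected until the dictionary hits an
exact target size (300 for the shipped reference dictionary). Because
the cluster count is a step function of λ, an exact hit can be
unattainable; in that case the smallest dictionary above the target is
reduced by merging its closest centre pair (the merge keeps a "crystal"
tag if either member carried one). In practice the bisection lands
exactly and the merge path is a rarely used tie-off.

Two details make the build strictly reproducible: every random choice
(pixel subsampling, k-means initialisation) is seeded, and each image's
stage-1 seed is derived from the image content, so duplicated training
images yield identical stage-1 centres that stage 2 collapses — a
duplicated corpus gives the same dictionary as a single copy.

DP-means is order-dependent; `dpMeans(restarts = n)` reruns the sweep
from seeded random point orders and keeps the lowest objective. The
exhaustive-partition equivalence asserted in the tests holds in the
separated regime the algorithm targets (compact clusters far apart
relative to λ); on unstructured noise DP-means, like any local method,
can miss the global optimum, and no restart budget fixes that.

## The image pipeline

Each droplet image passes through:

1. **Grey conversion and contrast stretch** to the full 0–255 range
   (`toGreyFullRange()`).
2. **Well registration** (`registerWell()`): the image is aligned to a
   per-subwell background (the pixel mean of empty-plate images,
   `buildBackground()`) by exhaustive integer translation minimising the
   mean absolute difference. The registered frame position is reused
   twice: to mask the frame for fault features and to suppress frame
   edges during segmentation.
3. **Fault detection** (`faultFeatures()`, `trainFaultClassifier()`):
   the frame-masked well interior is z-scored; the gradient magnitude
   image is summarised by four moments plus a 50-bin histogram of
   absolute gradients (unit-width bins centred 0–49, overflow clipped
   into the last bin) — 54 gradient statistics — and joined by six shape
   features of the segmented droplet (area, well-relative centroid,
   second-moment eccentricity, major/minor axes; zeros when
   unsegmentable). A seeded random forest flags empty wells, undersized
   drops and off-frame wells, which are excluded and logged.
4. **Droplet segmentation** (`segmentDroplet()`): gradient magnitude is
   computed on a lightly smoothed image, frame pixels are zeroed, the
   image is unwrapped to polar coordinates (1 px radial, 1° angular)
   about a seed point — the centroid of the background-subtracted
   foreground — and `circularShortestPath()` finds the closed contour
   maximising summed gradient. The DP is exact: it is run from every
   start row under a ±1 row/degree step constraint with circular
   closure. A result is rejected when its area falls outside 2–95% of
   the well interior, more than 10% of the boundary lies on the frame,
   or the area is under 40% of the background-subtracted foreground (the
   third test catches paths that collapse onto a dark precipitate mass
   — a failure the first two cannot see). Rejected drops are retried on
   a gamma-corrected image (low-pass σ = 10) and then on a blurred one;
   drops failing all three attempts are flagged unsegmentable.
5. **Shadow gamma correction** (`gammaCorrect()`): Î = 255·(I/255)^γ
   with per-pixel γ = clamp(imLP/255, 0.05, 1), where imLP is the
   Gaussian low-pass image (σ = 1 in the descriptor chain). The printed
   form of this correction in the source literature is incomplete; this
   reconstruction satisfies the stated behaviour — dark rim pixels are
   boosted in proportion to their local darkness, bright regions are
   fixed points, the map is monotone and range-preserving, and the 0.05
   clamp prevents blow-up in near-black regions. The σ = 10 variant used
   by the segmentation fallback flattens *wide* dark regions (the γ
   field tracks edges broader than σ) while sharp droplet rims survive —
   that spatial selectivity, not the intensity mapping itself, is what
   rescues drops with large diffuse precipitate masses.
6. **Boundary extension** (`extendBoundary()`): the cropped droplet is
   unwrapped to polar form about its centroid (R = half the larger
   bounding-box dimension; the polar image holds R + 13 rows so the pad
   always fits) and, per angular column, the 13 radial pixels beyond the
   boundary (half the 25 px filter support + 1) are set to the median of
   the ten innermost boundary-adjacent pixels — the median resists
   segmentation outliers. The ring is mapped back to Cartesian space so
   edge pixels gain a plausible neighbourhood for filtering, and is
   excluded from the histogram along with the filter border.
7. **Normalisation and scaling** (`normalizeAndScale()`): z-score to
   mean 0 / sd 1 over the droplet-plus-ring region, then bilinear
   downscale by 0.25 (per-imager configurable: an imager with roughly
   half the native resolution would use 0.5) to match the dictionary's
   working resolution.
8. **Descriptor** (`dropletDescriptor()`): filter, label against the
   dictionary, histogram.

## Ranking and profiles

`trainRanker()` fits a 500-tree random forest on raw histogram counts
(forests split scale-free per tree, so count normalisation is
unnecessary) with "interesting"/"uninteresting" labels; under the human
scoring convention, scores ≥ 3 (microcrystals and better) are
interesting and lower or missing scores are not (`labelsFromScores()`).
`scoreDroplets()` returns the interesting-class posterior;
`rankPlate()` sorts descending with ties broken by image id for a
reproducible viewing order, either per droplet or per well (a well takes
the maximum of its three subwells, which share chemistry).
`profileSummary()` reports, per score cutoff, the fraction of plates
whose first labelled crystal would be found and the mean fraction of
uninteresting droplets left unviewed — the confidence/effort trade-off
of inspecting only above-cutoff images.

## The synthetic image generator

All tests and the shipped reference dictionary rest on
`generateWell()`/`generatePlate()`, a seeded renderer of 384×384 px
subwell images: a dark rectangular frame with corner shadows and an
illumination gradient, a droplet disk with a dark rim shadow and a sharp
boundary step, Gaussian sensor noise (sd 2.5), and class textures chosen
to excite distinct filter channels — band-limited granular noise for
precipitates (mid-scale bar responses), bright convex polygons and
needles with straight high-gradient edges for crystals, 100–500 bright
specks for microcrystal showers, smooth dark blobs for phase separation,
plus the three fault classes (empty well, undersized drop, off-frame
well). Ground-truth droplet and crystal masks are emitted with every
image. Two stress variants exercise the segmentation fallbacks: drops
pushed against the frame, and heavily precipitated drops with a weak rim
(shadow depth 4 instead of 55 grey levels) containing a large
soft-edged dark mass (radius 48–60 px, depth 150, edge softness σ = 8)
whose diffuse edge out-competes the weak rim in the plain gradient image
but is flattened by the σ = 10 gamma correction.

`makeTexturePatch()` renders droplet-free texture patches for isolated
studies of the descriptor; its `rotation` argument re-renders the *same*
texture features in rotated coordinates, emulating a physical rotation
of the sample. The rotation-invariance checks use this rather than
pixel-resampling rotation: bilinearly rotating a rasterised patch
destroys 1–2 px speck content at the sampling limit, a loss of the
resampling rather than of the descriptor (192 px patches are used so
that the central comparison region carries enough specks for stable
histograms).

The generator emulates controllable statistical structure, not
photorealism: no refraction optics, no polarisation colour, no focal
blur, no skin formation, and class textures are stationary inside the
drop. Passing tests therefore demonstrate that the machinery — filters,
clustering, segmentation geometry, ranking — behaves as specified under
known ground truth; they do not certify performance on any particular
imager, for which the dictionary and both forests should be retrained
on real droplets. The shipped 300-entry dictionary
(`referenceDictionary()`, file `reference_textons_synthetic.tsv`) is
likewise a synthetic-corpus artifact, sized and structured like a
production dictionary.

## Problem sizes and numerical choices

The test and acceptance workloads use: 3 empty wells per subwell for
backgrounds; 100 droplets (seven condition groups) for segmentation
recovery; a 500-droplet training corpus and 300 held-out droplets on 20
plates of 15 for ranking recovery; 152 images (100 precipitation, 52
crystal-containing) for the reference dictionary, with 2000 response
vectors subsampled per image for stage-1 clustering. These sizes were
chosen as the smallest at which the statistical checks are stable.

Other numerical choices: convolution borders are handled by mirror
reflection, and responses within half a kernel support of the image edge
are excluded from all histograms; polar interpolation is bilinear, with
ring pixels lacking a polar antecedent filled from the nearest angular
column; registration ties are broken toward the smallest |dx|+|dy|, then
lexicographically; the segmentation cost uses summed gradient magnitude
along the contour (plain, rather than the extremal-mean-intensity
criterion of older droplet tracers, which is harder to make exact);
z-scores of constant regions are defined as zero; and all forests are
trained with fixed seeds, making every pipeline stage bit-reproducible
given its inputs.

## Known limitations

Segmentation assumes the droplet is star-shaped about the seed point (a
polar path has one radius per angle); extremely lobed or merged drops
violate this. The fault classifier and ranker shipped from synthetic
training transfer nothing to real imagers beyond their architecture.
The χ² distance and Euclidean nearest-texton rule are the field's
conventional choices, not optimised ones; alternative distances are an
open question. Detergent-style drops with near-invisible boundaries are
only partially represented by the weak-rim fixtures.
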