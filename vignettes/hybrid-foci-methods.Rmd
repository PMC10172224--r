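---
title: "Quantifying RNA:DNA hybrid foci: methods and design notes"
author: "HybridFoci package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA:DNA hybrid foci: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HybridFoci)
```

## The measurement problem

RNA:DNA hybrids detected by S9.6 immunofluorescence cannot be counted as
molecules: the antibody binds hybrids from ~8 bp upward with unknown
stoichiometry, so a fluorescent spot reports an unknown number of
molecules. The unit of analysis is therefore the *focus*: a discrete,
geodesically delimited object in the marker channel. Per cell and per
compartment (nucleus, cytoplasm) the pipeline reports

* **foci density** — object count normalized by the compartment area
  (per pixel, with a per-µm² companion derived from the pixel size);
* **foci intensity** — the mean over foci of each focus's mean pixel
  intensity, measured on the raw marker image (a.u.);
* **FGI**, the foci granulation index — the percentage of foci with
  1-pixel area, a descriptor of objects at the resolution limit;
* **nuclear cluster features** — objects above a dimension criterion,
  split into *perinuclear* (contiguous with the nuclear membrane) and
  *nucleolar* (interior) clusters, with counts and intensities;
* **local density indices (LDI)** — for every foci-mask pixel, the number
  of foreground neighbors in the minimal 3×3 window (0 = isolated,
  8 = fully connected), summarized as a 9-bin percentage histogram and
  rendered as a density distribution map (DDM).

## Segmentation procedure

Per field of view, both channels are maximum-intensity projected. Then:

1. **Nuclei** — the counterstain is preprocessed with either a local
   median map (window 5 px; for noisy material such as irradiated cells)
   or contrast-limited adaptive histogram equalization, thresholded with
   Otsu's criterion, eroded once (3×3; the "conservative" step), holes
   filled, and components below `min_nucleus_area` dropped.
2. **Whole cells** — the two channels are min–max normalized, fused
   (per-pixel maximum by default), and thresholded strictly above the
   histogram mode, which is the dominant background level. Cells are
   separated by a marker-controlled watershed: the distance-transform
   relief of the cell mask is flooded from the nucleus components, so
   every cell label contains exactly one nucleus. Foreground without a
   seed is discarded with a warning; cells touching the image border are
   dropped (a partially imaged cell biases per-cell features). The
   cytoplasm of a cell is its label minus its nucleus, making the two
   compartments disjoint by construction.
3. **Foci** — within one compartment, the marker image is restricted to
   the region (cytoplasm additionally gets a white top-hat, disc radius
   7 px, to remove smooth background shading), the local median map
   (window 3 px) is computed, and pixels whose map value strictly exceeds
   the third quartile (Q3) of the map inside the region become
   candidates. Candidate blobs are split into discrete foci by geodesic
   reconstruction: the regional maxima of the median map (8-connected,
   with h-maxima suppression of one quantization step to merge plateau
   duplicates) seed a priority flood of the inverted map, and each focus
   is the influence zone of one maximum. Areas and intensities are always
   measured on the raw marker image.
4. **Nuclear classification** — nuclear objects whose area strictly
   exceeds `cluster_area_threshold` are clusters; a cluster with a pixel
   8-adjacent to the morphological internal gradient of the nucleus mask
   is perinuclear, otherwise nucleolar.

The strictly-above-Q3 rule has two useful consequences: a constant region
yields no foci (Q3 equals the maximum), and the candidate set can never
exceed a quarter of the region (plus ties). Its flip side is an
occupancy-adaptive threshold: the more of a region the signal covers, the
higher Q3 rises, eroding faint object skirts first.

### Why the background must be quantization-dark

The Q3 rule only isolates *discrete* objects when the local median map of
the background is essentially constant: Q3 then falls on that constant
and strictly-above selects signal alone. If background flux is large
enough that the median map fluctuates across several gray levels, the
75th percentile sits inside the noise and the rule flags ~25 % of every
region regardless of content. Offset-subtracted confocal acquisitions
with long exposure and frame accumulation are in the first regime — dark
compartments, photon-limited spots — and that is the regime the
synthetic generator emulates.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `median_window` | 3 | px | smallest odd window; preserves 1-px foci that the FGI counts |
| `median_window_nuclei` | 5 | px | stronger smoothing for the nucleus-scale structure |
| `tophat_radius` | 7 | px | larger than any focus, smaller than cytoplasmic shading |
| `cluster_area_threshold` | 20 | px | the dimension criterion; mandatory, logged, must be matched to the data (see below) |
| `fusion_rule` | max | — | keeps either channel sufficient for cell foreground |
| `min_nucleus_area` | 50 | px | rejects debris at 0.1 µm/px |

The dimension criterion has no universal value: it is set by scouting the
images, exactly as the nuclear cluster concept requires. For the
synthetic study conditions shipped with the package the criterion is
40 px, placed in the gap between the largest generated focus footprint
(~25 px) and the smallest generated cluster footprint (~50 px); every run
records the value used in its log.

## The synthetic study conditions

`fieldSpec()` renders 224×224 px fields (0.1 µm/px) of 4 non-touching
cells: elliptical nuclei (semi-axes 18–22 px) with multiplicative
low-frequency counterstain texture (level 100 counts ± 20 %), cytoplasm
as a 10 px dilation ring carrying faint counterstain spill (8 counts),
and marker objects on a dark background:

* extended foci: isotropic Gaussian spots truncated at 3σ (σ 0.7–1.0 px
  nucleus, 0.6–0.9 px cytoplasm; peak ≈ 64 counts);
* 1-pixel-class foci (25 % of foci): resolution-limited point sources
  rendered as a peak with a 4-neighbor skirt at a quarter peak. Their
  local median map has exactly one-pixel support, so they segment to
  area 1 — a literal single-pixel impulse would be erased by any median
  filter (its window median is background), and cannot exist in a real
  diffraction-limited image either;
* perinuclear clusters (σ 2.0–2.6 px, peak ≈ 200) centred 4–8 px inside
  the nuclear boundary — deep enough that the conservatively eroded
  nucleus mask retains the bulk of the cluster — and nucleolar clusters
  ≥ 13 px deep;
* Poisson shot noise on all mean counts plus rounded Gaussian read noise
  (σ 0.2). Peak SNR is photon-limited: peak/√peak ≈ 8 at the default
  peak. Object counts are Poisson draws truncated at per-compartment
  packing caps, and dart-throwing placement enforces per-class keepout
  radii; objects that cannot be placed after bounded retries are simply
  not planted (the ground truth lists exactly what was rendered), while
  a request that has no admissible location at all raises an
  overcrowding error.

Condition profiles shift these parameters in the direction of the
treatment effects they emulate: a hyperbaric-oxygen-like arm doubles
nuclear focus peak intensity and raises cluster rates; a hypoxia-like arm
raises counts with dimmer peaks and tighter packing; an irradiation-like
arm lowers counts and intensity. The profiles are qualitative,
sign-level analogues — they make no attempt to reproduce any measured
effect magnitude, because the original image set is not available and
desk-scale simulation cannot stand in for it.

What the generator deliberately does **not** model: optical PSF beyond
the minimal point-source kernel, axial structure (fields are rendered in
2-D and split into z-sections only for I/O round-trips), autofluorescence
gradients, touching or overlapping cells, mitotic figures, and
segmentation-confounding debris. Passing tests on these fields therefore
demonstrate the correctness of the algorithms under the stated imaging
model, not performance on arbitrary real material.

## Numerical choices

* All object connectivity is 8-neighbor, consistent with the 3×3 LDI
  window whose maximum is 8.
* The median filter replicates edges; the DDM instead treats image
  borders as background, so masks touching the border report lower LDI
  (documented behavior, relevant only to cells that would be dropped by
  border QC anyway).
* Watershed and influence-zone floods break ties by insertion order of a
  FIFO priority queue (raster order at equal relief), making every label
  image deterministic.
* h-maxima suppression uses h = 1 quantization step — the smallest value
  that merges plateau duplicates without suppressing genuine maxima.
* Q3 uses the default quantile definition (type 7) over all region
  pixels, not only nonzero ones; with a dark background the two
  populations coincide for practical purposes.
* Undefined features (intensity or FGI of a cell without foci, intensity
  of an absent cluster class) propagate as missing values into the CSV
  and are excluded pairwise from statistics; zero-imputation would bias
  intensity downward.
* Shapiro–Wilk gating treats a constant sample as non-normal (the test
  itself is undefined there); when exactly one group passes the gate the
  comparison falls back to the rank-sum branch, the more conservative
  choice.
* The Wilcoxon branch is exact for both n ≤ 20 without ties and uses the
  tie-corrected normal approximation with continuity correction
  otherwise. Bonferroni multiplies by the family size m — the number of
  condition-vs-control comparisons — and caps at 1; m is a required,
  logged run parameter because no universal family is implied by the
  data layout.
* Effect direction and percent change use the location matching the test
  branch: means for Student's t, medians for the rank-sum test.

## Validation problem sizes

The shipped tests validate the pipeline end to end at sizes chosen for a
single CPU: spot-recovery over 100 seeded 192×192 fields of 3 cells
(count exactness and sub-pixel centroid agreement), exact FGI on
zero-noise fields, null calibration of both test branches at 1000
replicates of n = 100, and 20 replicates of a 100-cell-per-arm
hyperoxia-like vs control comparison. The LDI boundary cases (isolated
pixel → 0, fully connected centre → 8) and a 200-mask brute-force
equivalence pin the DDM implementation.

## Known limitations

* The occupancy-adaptive Q3 threshold couples object footprints to
  regional signal load; heavily occupied nuclei shrink faint skirts,
  which is faithful to the method but means absolute areas are not
  comparable across very different occupancy regimes.
* FGI exactness at the resolution limit holds in the photon-limited
  regime; under heavy noise an isolated point source occasionally gains
  or loses a skirt pixel, jittering its area between 1 and 2.
* The watershed relief is the distance transform of the fused-channel
  mask; strongly concave cell shapes may split differently than an
  intensity-relief watershed would.
* Statistics treat cells as independent replicates, as the feature
  tables do; per-field random effects are out of scope.
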