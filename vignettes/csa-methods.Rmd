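---
title: "Measuring myofiber cross-sectional area: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring myofiber cross-sectional area: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibercsa)
```

## The measurement problem

Muscle regeneration is scored histologically through the cross-sectional
area (CSA) of myofibers in transverse cryosections. Immunostaining the
basal-lamina protein laminin draws a bright ridge around every fiber,
leaving interiors dark. Segmenting fibers is therefore a matter of
separating dark interiors from the bright boundary network — easy on
uninjured muscle, where fibers are large, polygonal and tightly packed,
and hard on regenerating or dystrophic muscle, where fibers are small,
round, extremely variable in size, and separated by wide interstitial
space that the automation readily mistakes for fibers.

`fibercsa` implements a semi-automated workflow: a deterministic automated
pipeline, followed by programmatic manual correction. The experimenter is
treated as the authority — hand-added fibers bypass every automated
filter. A key point the package is built to demonstrate: CSA should be
measured on the *whole* section, because regeneration after toxin injury
proceeds centripetally and any spatial subset of the section yields a
biased mean.

## The automated pipeline

`run_pipeline(image, config)` composes six deterministic stages; two runs
on the same inputs are bit-identical.

**Thresholding.** The gray threshold minimizes the Huang–Wang fuzziness.
For each candidate `t`, pixels split into classes `<= t` / `> t` with
means $\mu_0(t), \mu_1(t)$; a pixel of gray $g$ has membership
$u = 1/(1 + |g - \mu|/C)$ to its class, with $C = g_{max} - g_{min}$, and
the criterion is $\sum_g h(g)\, S(u(g))$ with
$S(u) = -u\ln u - (1-u)\ln(1-u)$. Ties are broken toward the smallest
gray level, which matters on noise-free synthetic images where whole
plateaus of thresholds are equivalent. 8-bit images use one bin per gray
level; 16-bit images use 256 equal bins spanning `[min, max]` (the common
8-bit-scaled behavior), and the returned threshold is the largest gray
level of the minimizing bin so that thresholding reproduces the bin
partition exactly. A constant image has no valid partition and raises a
degenerate-image error rather than returning a silent value.

**Binarization.** Laminin is bright, so fiber interiors are `g <= t`. With
the default `invert_after_threshold = TRUE` the interiors become the
foreground particles; the flag exists because the same machinery can
analyze the ridge network itself.

**Opening, hole filling.** A binary opening with a square element of side
`2*open_radius_px + 1` (default 3×3, one iteration) detaches thin
bridges through ridge gaps and smooths contours; it is anti-extensive and
idempotent, both property-tested. Hole filling converts every background
component not 4-connected to the image border into foreground, so each
fiber interior becomes a solid particle while interstitial background
(always border-connected in practice) is preserved. Foreground uses
8-connectivity and background 4-connectivity — the standard complementary
pair that keeps the two tessellations consistent.

**Morphometry.** The area of a particle is its exact pixel count times
`pixel_size_um²` — never a polygon approximation. The outer contour is
traced along the *cracks* between pixels (vertices at integer lattice
corners), which has two exact properties: the polygon's shoelace area
equals the pixel count, and a pixel is inside the polygon iff its center
is — so ROIs rasterize back to their exact pixel sets. The perimeter is
the length of the crack contour after Douglas–Peucker simplification with
a 1-pixel tolerance. This estimator was calibrated on closed forms: it is
exact on axis-aligned rectangles (a 10×10 µm square gives perimeter 40 µm
and circularity $4\pi A/P^2 = \pi/4 \approx 0.785$) and within a few
percent on rasterized discs (radius 50 px → circularity 0.98; radius
8 px → 0.91). A raw crack length would inflate disc perimeters by 27%
(circularity 0.62), while a pixel-center chain would *shorten* square
perimeters (circularity 0.97); the simplified-contour estimator is the
only local-free choice we found that is accurate on both shape families.
Circularity is capped at 1.0, since discretization can push tiny regions
above it.

**Filtering.** A particle is kept iff `area ≥ size_min_um2`,
`circularity ≥ circularity_min`, and (default) it does not touch the
border — only entire myofibers are analyzed. Rejects carry all applicable
reason codes (`too_small`, `not_circular`, `edge`), and the run records
per-reason counts. The presets mirror the recommended starting thresholds
per condition (D0 200, D8 50, D14 100, D28 150, Fib-mdx 50 µm², all at
circularity 0.4); for regenerating muscle they are starting points meant
to be lowered if small fibers are missed. Because filtering is calibrated,
`pixel_size_um` is required; a missing calibration falls back to 1 µm/px
with a warning.

## Tiling whole sections

Whole-section scans can exceed what one pass should process, and splitting
also helps when staining intensity varies across a section. `split_into_tiles`
produces 2 tiles (along the longer axis) or 4 quadrants; the earlier tile
is extended by `overlap_px` across the seam, and offsets map tile
coordinates back exactly. `cmd_segment` computes *one* global Huang
threshold and fixes it for all tiles, so tiling never changes the
binarization. `merge_tile_results` shifts ROIs into whole-image
coordinates and deduplicates seam-zone fibers: two ROIs from different
tiles are the same fiber when either centroid falls inside the other's
polygon; the copy farthest from its own tile's internal seams wins (a
seam-cut copy never beats an intact one; area and tile index break
residual ties). When the overlap exceeds the largest fiber diameter,
every fiber is intact in at least one tile and the merged result equals
the untiled run — the suite asserts equal counts and total area within
0.1%.

## Manual correction and ROI interchange

`delete_fibers` and `add_fiber` record every event in an ordered
correction log; replaying the log onto the automatic result reproduces
the corrected result exactly (`replay_corrections`), which is also how
`correction_burden` verifies that two results are related before
computing the percentage of false fibers deleted and missed fibers added
(relative to the corrected count, as correction effort is reported).
Hand-drawn polygons are validated (simple, ≥3 vertices, within bounds,
nonzero area), measured by continuous shoelace geometry — which may
differ from a rasterized count by a sub-boundary-width amount — and are
exempt from size/circularity filters; their circularity is not computed
(`NA`), as it plays no role in CSA.

Results serialize to a zip archive of JSON records plus a manifest. The
writer is built into the package (stored entries, CRC-32, fixed
timestamp), making archives byte-reproducible; numbers are written with
17 significant digits so vertex coordinates round-trip bit-exactly.
ImageJ `.roi` polygon records and `.zip` archives of them import as
manual fibers, following the published binary layout (magic `Iout`, type
byte, int16 bounding box and relative coordinates from byte 64); writing
ImageJ format is intentionally not supported.

## The synthetic section generator

The paper-style validation data (microscopy) cannot ship with a package,
so every stage is validated against synthetic sections with exact ground
truth, `generate_section(section_params(...))`:

1. **Size law.** Target areas are lognormal (median and log-sd in µm²),
   optionally a mixture for bimodal fibrotic regimes. The canvas is sized
   to the sampled areas (or given explicitly; an impossible packing
   raises an error).
2. **Placement.** Seeds are dart-thrown largest-first with a separation
   of 0.68 of the summed equivalent radii. In `centripetal` gradient mode
   a candidate position is also required to match the seed's area
   quantile with the position's distance-from-center quantile (empirical,
   over the canvas), so small fibers settle centrally and large ones
   peripherally *without changing the area law's marginal*.
3. **Territories.** Pixels are assigned by a power (Laguerre) diagram with
   per-fiber weights, iterated four times toward the sampled areas
   (`w += (target - realized)/π × 0.9`). Power cells are convex, so every
   territory is connected; realized medians land within a few percent of
   the law (the suite asserts 15%).
4. **Rendering.** With interface distance `D` (distance transform of the
   inter-cell boundary), the truth label keeps `D ≥ roundness` — so
   `roundness = 0` gives tightly packed polygons whose truth areas are
   exactly the tessellation-cell pixel counts, and larger values give
   round fibers with interstitium ≈ `2*roundness` wide. The laminin
   ridge is rendered at `|D - roundness| < boundary_width_px`,
   straddling each fiber's edge; deep interstitium stays at the interior
   intensity, which is precisely what produces the characteristic
   false-fiber detections in wide-interstitium regimes. Gaussian noise is
   added last and clipped to the bit depth.
5. **Faint staining.** A fraction of fibers receives one contiguous arc
   (default half the boundary) where the ridge drops to the faint
   intensity — by default the background level, i.e. locally undetectable
   staining. Coherent arcs, not per-pixel dropout, reproduce how weakly
   stained areas appear in real sections. With the threshold fixed from a
   clean section, recall declines monotonically in `faint_fraction`
   (≈100% → 36% → 10% at 0/0.2/0.4 in the acceptance run); a partial-
   contrast default would sit above the fixed threshold of a noise-free
   section and produce no failures at all, which is why full local
   dropout is the default and the intensity remains a parameter.

Per fiber, the truth table reports the exact full-territory area
(`area_um2`, the label pixel count), the interior area inside the stained
band (`area_interior_um2`), centroid and border contact.

**What the generator does not emulate**: optical blur (PSF), vignetting
and stitching seams, non-Gaussian camera noise, nuclei or second
channels, partial fiber loss, staining gradients other than the faint
arcs, and genuinely irregular (non-convex) fiber outlines. Passing tests
on synthetic sections therefore demonstrates the *algorithmic* contracts
— thresholding, morphology, measurement, merging, correction — not
robustness to every optical artifact of real microscopy; the recommended
thresholds still need adjustment on real data, as the presets themselves
advise.

## Evaluation methodology

`match_to_truth` matches predictions to truth one-to-one, greedily by
descending intersection-over-union with a floor (default 0.5); IoU is
computed on exact pixel sets (predictions rasterize exactly, see above).
A visual matching, as done when judging segmentations by eye, is
irreproducible; greedy-IoU is the standard reproducible surrogate, and on
small instances it is tested against a brute-force assignment oracle.
Unmatched truth fibers are *missed*, unmatched predictions *false*; the
conservation identities `matched + missed = truth` and
`matched + false = predicted` hold by construction and are asserted on
every report.

Recall is reported over *eligible* truth — fibers at least `size_min`
large and not border-touching when edges are excluded — because fibers
the configuration deliberately filters cannot be recovered by design.
The truth-area convention is declared per report: `boundary_inclusive`
(full territory) shows the automatic pipeline's systematic slight
underestimation, since the pipeline measures inside the basal-lamina
band; `interior` isolates measurement accuracy proper (≈ −0.3% mean-CSA
error on clean sections).

Agreement between two per-image mean-CSA series uses the squared Pearson
correlation plus the least-squares line (for simple regression the two
R² notions coincide; Spearman is available as an option).
`subset_bias` partitions fibers by centroid (halves, quadrants, or a
central disc holding half the image area vs the periphery) and reports
each subset's percent deviation from the whole-section mean; on gradient
sections the periphery is biased up and the center down, the reason
whole-section analysis is necessary.

## Numerical choices and degenerate inputs

- Huang ties → smallest gray level; constant images → explicit error.
- Circularity capped at 1.0; perimeter simplification tolerance 1 px.
- 8-connected particles / 4-connected background; labels numbered in
  raster order of first pixel.
- Empty results: `mean_csa` errors; distributions return zero counts.
- Empty spatial subsets are flagged, never silently dropped.
- Multi-channel input is rejected with an instruction to extract one
  channel; 8- and 16-bit TIFF and 8-bit PNG are read.
- RNG: the generator seeds `set.seed` locally and restores the caller's
  RNG state; everything else is deterministic.

## Problem sizes used by the validation suite

The test suite and `scripts/acceptance.R` use sections of ~500 fibers
(≈ 1 Mpx) for detection/tiling/subset checks, 300 fibers for the
faint-staining series, 60-fiber sections for fast unit-level checks, 200
random histograms for the threshold oracle, and 100 random masks per
morphological law. These sizes give stable statistics (binomial noise on
a 500-fiber recall is ≈ 1%) while keeping a full run in the order of a
minute or two on one CPU.

## Known limitations

- Circularity values are estimator-specific; other tools' corner-weighted
  perimeters differ by a few percent, so the 0.4 filter may need
  recalibration when matching results across tools (it is a parameter).
- Merging assumes the tile overlap exceeds the largest fiber diameter;
  fibers larger than the overlap can be cut in every tile and are then
  dropped by the edge filter (or kept cut, if edges are included).
- The pipeline measures inside the stained band; comparisons against
  boundary-inclusive references will show a systematic negative offset
  that is a convention, not an error.
- ImageJ ROI support covers polygon-family records only, read-side.
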