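---
title: "Automated morphometry of tube formation assays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated morphometry of tube formation assays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubemorph)
```

## The measurement problem

Endothelial cells plated on a basement-membrane gel (Matrigel) self-organize
within 24–48 h into capillary-like tube networks. The standard readouts of
this tube formation assay (TFA) — total tube length, tube area, average
thickness, and the number of branch points — are usually obtained by manual
tracing, which is slow (hours per data set) and shows large inter-operator
variability, especially on poorly formed networks. tubemorph quantifies
bright-field TFA micrographs automatically, without fluorescent labels, so
that a whole study can be analyzed with a single reusable parameter profile
and zero per-image interaction.

## The processing model

Each image passes through a fixed, deterministic sequence:

1. **Load and convert.** The TIFF is read as three intensity planes and
   averaged pixel-wise into one grayscale matrix. The result is linearly
   stretched so its minimum and maximum equal the global intensity range of
   the source image. The stretch target is a documented interpretation: the
   package maps the grayscale extremes onto the extremes over all source
   channels, skipping the stretch entirely for zero-dynamic-range images.
   TIFF is required because lossy compression blunts exactly the
   high-frequency intensity changes the next step detects.

2. **Tube detection.** Tubes differ from the gel background chiefly by their
   borders, not by a global intensity offset (Matrigel is rarely flat, so
   global thresholds fail). Edges are therefore found with the Canny method:
   Gaussian smoothing (`sigma`, default 2 px), Sobel gradients, non-maximum
   suppression along the gradient direction, and hysteresis linking. The
   hysteresis thresholds are derived per image from the gradient-magnitude
   histogram (Otsu for the high threshold, low = 0.4 × high); these two
   settings are advanced arguments of `cannyEdges()` rather than profile
   parameters, since in practice they rarely need adjustment. The edge mask
   is then bridged (closing with a disc of radius `cannyConnect`), closed
   again with a disc of radius `dilate` to merge nearby objects, hole-filled
   (`fill`), and speck-cleaned (`clean`).

3. **Skeletonization.** The tube mask is eroded to a one-pixel-wide backbone
   by iterative removal of border pixels, forbidding any removal that would
   split an object, merge two objects, or change a hole — i.e. the Euler
   characteristic is preserved. The simple-point test is the Hilditch
   crossing number for an 8-connected foreground; border pixels are scanned
   in alternating N, S, W, E sub-iterations to avoid directional bias, and
   the iteration runs to a fixed point, which makes the operation idempotent.
   Spur clipping then removes up to `clip` pixels inward from every skeleton
   endpoint, stopping early at a branch point; `clip = Inf` repeats until
   nothing changes, which deletes branch-free fragments entirely while
   junction cores survive.

4. **Metrics.** Total length sums every distinct 8-adjacency of backbone
   pixels: orthogonal pairs count 1 pixel length, diagonal pairs 1.414 (the
   literal constant, kept for fidelity with the published weighting; it
   differs from √2 by < 0.02 %). Diagonal adjacencies already joined through
   a shared orthogonal neighbour are skipped, so an L-corner is not counted
   twice. Branch pixels are backbone pixels with ≥ 3 neighbours; they are
   consolidated by single-linkage clustering at distance ≤ `radius` and each
   cluster is reported as one branch point at the mean coordinate. Tube area
   counts only mask components whose intersection with the backbone holds at
   least `overlap` pixels — an object must contribute to the length to count
   toward the area. Average thickness is area / length, zero for an empty
   image and undefined (`NA`) if area is positive while length is zero.

## The parameter profile

All eight tunables live in a `ParameterProfile`, saved as flat JSON
(`saveProfile()` / `loadProfile()`, with `Inf` serialized as the literal
token `"Inf"`). Defaults sit at the midpoint of each parameter's typical
working range (taking 5000 and 10000 as the upper ends of the open-ended
`fill`/`clean` ranges); they are a starting point for interactive tuning on
one representative image, after which the saved profile drives the whole
batch. `fill` and `clean` are pixel **areas** and both thresholds are strict
("smaller than"), so a component of exactly the threshold size survives;
`overlap` is inclusive (≥).

Two analyses of the same image with the same profile are bit-identical: the
pipeline contains no randomness.

## Connectivity conventions

Foreground objects are 8-connected throughout. Holes, however, are
4-connected background components — the topological dual of an 8-connected
foreground. The dual convention is load-bearing: a thin Canny ring with
diagonal sections does not 4-enclose any leak path, so its interior can be
filled, whereas under an 8-connected background the interior would "escape"
between diagonally adjacent ring pixels and `fill` could never act on Canny
output. Axis-aligned test rings behave identically under either convention.

## The phantom generator

Validation uses images generated in silico with exactly known truth.
`phantomSpec()` describes a set of straight strokes; `renderPhantom()`
rasterizes each stroke as a hard-edged capsule (every pixel centre within
half the stroke width of the segment, no anti-aliasing). The capsule shape
is deliberate: its medial axis is exactly the generating segment, so the
analytic segment length is precisely what an ideal skeleton should measure,
and ground truth comes from geometry — never from running the pipeline.
Junction truth counts points where at least three stroke directions meet
(a crossing contributes two per passing segment, a terminating segment one),
merging junctions closer than the consolidation radius. Area truth is the
rasterized stroke count, since rasterization itself is exact. Salt-and-pepper
noise flips each pixel to black or white with the requested density under a
fixed seed, and `addIlluminationGradient()` can overlay a linear intensity
ramp on a rendered image for robustness experiments (off by default).

`validationSuite()` renders 22 noiseless archetypes (straight lines at 0°,
45°, 90°, 135°; T, Y, X and plus junctions; parallel pairs; 2×2 and 3×3
grids; H, ladder and comb networks; a chevron, a staircase curve, a closed
loop, and a blank control) plus three noisy variants, in 512×512 images with
5-px strokes. Junctions are spaced farther apart than the consolidation
radius so the analytic count equals the expected consolidated count.

`phantomProfile()` is the profile tuned on this suite — small area
thresholds, `clip = 0`, consolidation radius 30 — mirroring how a profile is
tuned for any data set. With it, total length and branch-point count agree
with truth to within 1 % on every noiseless phantom (the suite minimum is
about 99.1 %), which `scripts/acceptance.R` recomputes from scratch.

## What the phantoms do and do not show

Phantoms emulate the geometry of tube networks (elongated branched
structures with strong borders) but not cell texture, debris, bubbles,
Matrigel autofluorescence, or uneven illumination. Passing the suite
demonstrates that the measurement chain — detection, topology-preserving
thinning, adjacency-weighted length, junction consolidation, overlap-gated
area — is unbiased on clean geometry; it does not by itself establish
accuracy on real micrographs, where profile tuning and retrospective review
of the overlay images remain the user's responsibility.

## Numerical choices and known limitations

* **Orientation bias of the length rule.** The (1, 1.414) adjacency
  weighting is exact for structures at multiples of 45° and overestimates
  intermediate orientations (up to ~8 % near 22.5°) — a property of the
  published weighting itself, not of this implementation. The validation
  suite therefore uses the archetype orientations; real networks with
  isotropic orientation carry a small positive length bias.
* **Corner rounding.** Discrete thinning rounds sharp (≤ 90°) corners
  between oblique strokes by ~2.5 px per corner, so polyline archetypes in
  the suite keep corners either obtuse or few relative to their length.
* **Tip erosion and rotation.** Directional sequential thinning processes
  row borders before column borders, so a bar's tips may erode one pixel
  more in one orientation than the other; the centerline position is exact
  and the length difference is bounded by one pixel per tip. A 45°-rotated
  line measures within 2 % of its unrotated twin.
* **Edge halo.** Canny localizes edges about one pixel outside a hard
  boundary on each side, so detected bands run ~2 px wider than drawn
  strokes; thickness estimates inherit this positive bias (relatively
  smaller for wider tubes), and the area/length definition of thickness
  slightly exceeds the drawn width for capsule-ended strokes.
* **Saturated pixels** flatten the local gradient and can suppress true
  edges; images should be acquired without clipping.
* **Scan-order determinism.** Node consolidation is single-linkage, whose
  clusters are scan-order-independent; raster-order seeding merely fixes
  the output ordering.

## Operating modes and outputs

`analyzeImage()` is the single-image "sandbox"; `runBatch()` applies one
profile to a file list, writes a CSV report (`file, length_um, area_um2,
n_nodes, thickness_um, error`), logs one structured line per image, never
aborts on a single bad file, and optionally writes the four overlay TIFFs
(detected edges; backbone dilated by 10 px; inverted surviving-area mask;
consolidated nodes dilated by 10 px) into per-type subdirectories for
retrospective review. The report is CSV rather than a spreadsheet binary so
that downstream tooling can consume it directly. For images with a black
surround (retinal fundus photographs), `roiMode = "nonblack"` restricts
detection to pixels above a luminance threshold (default 10/255), eroded by
3 px to suppress the artificial gradient at the surround boundary; nothing
else in the pipeline changes. Optic-disc exclusion is deliberately out of
scope.

Problem sizes used by the shipped tests and the acceptance script — 512×512
phantoms for the suite, 64×64 masks for the randomized topology battery —
were chosen so the full validation runs in well under a minute per batch on
a single CPU while keeping end effects (tips, corners) below the 1 %
validation bar.

```{r example, eval = FALSE}
library(tubemorph)

# tune once on a representative image, then persist the profile
prof <- parameterProfile(scale = 1.8, cannyConnect = 8, dilate = 4,
                         fill = 1000, clean = 5000, clip = 50,
                         overlap = 10, radius = 60)
saveProfile(prof, "study_profile.json")

# fully automated batch over a study
report <- runBatch(list.files("images", pattern = "\\.tif$", full.names = TRUE),
                   loadProfile("study_profile.json"),
                   outDir = "results", saveImages = TRUE)
read.csv(report)

# validate the installed pipeline against analytic phantoms
writeValidationSuite("phantoms", scale = 1, seed = 1)
rec <- analyzeImage(file.path("phantoms", "grid3.tif"), phantomProfile())
metrics(rec)
```
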