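---
title: "Measuring planar cell polarity from binary masks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring planar cell polarity from binary masks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarcell)
```

## The model

`polarcell` treats a segmented micrograph as a binary grid: foreground
("chunk") pixels are cell surfaces or other planar features of interest,
background pixels are everything else. A cell's polarity is carried by a
*cave* — background pixels enclosed within the chunk, such as the
unlabeled fonticulus of a βII-spectrin-stained hair cell — and the
polarity angle is simply the direction of the vector from the chunk's
center of mass to the cave's center of mass:

$$\theta \;=\; \operatorname{atan2}\!\big(\bar y_{chunk} - y_{cave},\;
x_{cave} - \bar x_{chunk}\big)$$

with the y-difference negated because image y grows downward; 0° then
points east on screen and 90° north, matching how microscopists orient
their images. Both centroids are plain arithmetic means of pixel
coordinates — no shape model, no fitting — which is what makes the method
robust across tissues (hair cells, ommatidia, ependymal cilia patches)
and across stains, at the price of requiring a well-thresholded binary
input.

Assumptions worth stating explicitly:

* one cave (after selection) represents one cell's direction; multi-cave
  averaging is deliberately out of scope;
* the chunk and cave centroids differ — a perfectly concentric inclusion
  has no direction and the cell is reported in the Bad Count rather than
  guessed;
* upstream preprocessing (z-projection, background subtraction,
  thresholding, outlier removal) has already happened in the user's
  imaging tool; the package only offers a minimal threshold (fixed or
  Otsu) for convenience.

## Pipeline order and the parameters that matter

Stages run in a fixed order: chunk detection → size exclusion → doublet
splitting → border exclusion → plastic wrap → centroids → cave
detection/filtering/selection → angles → statistics. Size exclusion sees
pixel counts *before* wrap pixels exist; centroids and bounding boxes see
pixels *plus* wrap, since bridging pixels count as cell mass.

| parameter | default | unit | why this default |
|---|---|---|---|
| `min_chunk_px` | 500 | px | noise floor used for cochlear hair cells at high magnification |
| `border_margin_px` | 10 | px | discards cells that did not fully enter the frame |
| `doublet_ratio` | 2.0 | – | cochlear doublets are about twice as wide as tall; vestibular work used 1.5 |
| `plastic_wrap` | on | – | required for open concavities; harmless for closed cells |
| `min_cave_px` | 15 | px | ignores speckle pockets created by thresholding |
| `cave_criterion` | largest | – | robust default; compass criteria (e.g. northmost) suit oriented epithelia |
| `angle_range`/`direction` | 0–360 CCW | deg | 90° = north on screen |
| `rose_bin_width` | 15 | deg | 24 wedges; purely presentational |

**Connectivity.** Chunks are 8-connected (diagonally touching foreground
joins one cell — thresholded surfaces routinely touch corner-to-corner);
caves are 4-connected. This is the standard digital-topology pairing: if
both used the same connectivity, a diagonal gap could simultaneously count
as "connected boundary" and "leak path", making enclosure ill-defined.

**Doublet splitting.** A fused pair is recognized purely by bounding-box
aspect ratio relative to the image axes and cut at the midline; pixels
strictly left of (above) the line form the first half, midline pixels the
second — deterministic and partition-preserving. The heuristic degrades as
a doublet's axis approaches 45° and never recurses, so triplets and larger
aggregates should be removed by size exclusion instead.

**Plastic wrap.** The intent is to close "breaks in the arc of the
perimeter" so that an open indentation (a U-shaped stereocilia bundle, the
mouth of an ommatidium) becomes a measurable cave. We realize this as
convex-hull bridging: rasterize each hull edge of the chunk's pixel set
with Bresenham lines and deposit the line's non-chunk pixels as wrap. One
subtlety is genuinely a design decision: for a *digitally* convex shape
(a rasterized disk), hull chords between neighboring boundary vertices
routinely step onto background pixels right at the rim. Bridging those
would violate two properties we consider definitional — wrapping a convex
chunk is the identity, and wrapping twice adds nothing — so an edge only
bridges when some pixel of its line is neither chunk nor 8-adjacent to
chunk, i.e. when it spans a real gap deeper than one pixel. Shallow one-
pixel dents are consequently not wrapped, which also avoids manufacturing
one-pixel caves.

**Cave enclosure.** A cave is background unreachable from outside the
chunk's filled region without crossing chunk or wrap pixels (flood fill
from the rim of the padded bounding box). Pixels of *other* chunks are
passable during this flood: a pocket sealed only jointly by two
neighboring cells belongs to neither. Caves merging a natural pocket with
a wrap-created one inherit the `wrap_created` origin. Cave selection
breaks ties by larger size, then smaller centroid y, then smaller x, then
detection order — arbitrary but documented and stable.

**Circular statistics.** With $C=\sum\cos\theta_i$, $S=\sum\sin\theta_i$,
$R=\sqrt{C^2+S^2}$: mean angle $=\operatorname{atan2}(S,C)$, resultant
mean length $\bar R = R/n$, circular variance $1-\bar R$, circular SD
$\sqrt{-2\ln\bar R}$ reported in degrees (the dispersion column published
for this kind of data is in degrees). These are the classical Fisher
descriptive statistics; inferential tests are out of scope. When $\bar R$
vanishes (antipodal data) the mean is undefined: we clamp $\bar R$ below
$10^{-12}$ to zero, return `NaN` with a warning, and report infinite SD
rather than an arbitrary direction.

## What the synthetic generator emulates — and what it does not

`make_tissue()` builds binary masks of disk-shaped cells with an interior
circular cave displaced along a known bearing, placed without overlap by
bounded rejection sampling; `make_u_cell()` builds open-mouthed annuli
(phalloidin-like bundles) and `make_doublet()` axis-fused pairs. Bearings
can be fixed, uniform, or von Mises (sampled with the Best–Fisher
rejection algorithm, since no circular-statistics package is assumed).

The default geometry is chosen once as a realistic stated world for a
high-magnification confocal mask: cell radius 17–20 px, cave radius 6 px
(roughly a third of the cell diameter, like a fonticulus), cave offset
8–10 px (eccentric, about half the radius, as the fonticulus sits toward
the cell's lateral edge). Two self-consistency constraints drove the
exact numbers. First, a cell minus its cave must clear the default 500 px
noise floor with margin (here ≥ 760 px). Second — less obvious — the
*measurement discretization error* must stay below the 2° tolerance the
package promises for ground-truth recovery. The dominant error term is
the rasterized cave's centroid, which jitters by ~0.2 px as the continuous
cave center moves sub-pixel; dividing by the polarity vector length gives
an angular error of roughly $0.2/d$ radians. A small cave (radius 3) at
offset 4 produces worst-case errors above 4°, a radius-6 cave at offset
8–10 stays below 2° (empirical maximum 1.8° over 16,000 random cells).
Rasterization itself uses the pixel-center rule (a pixel belongs to a
disk iff its center does), so geometric oracles can be computed exactly.

What the generator does *not* emulate: point-spread blur, shot noise,
uneven illumination, partial thresholding artifacts, touching cells
beyond clean axis-aligned doublets, or non-circular cell outlines. A
green test therefore establishes that the *algorithmic* chain — labeling,
filtering, wrapping, enclosure, centroids, angles, statistics, I/O — is
correct on ideal segmentations; it says nothing about how well a real
micrograph thresholds. That judgment stays with the user, which is why
annotated and overlay images exist.

## Numerical and format choices

* Angles are written to 3 decimal places in CSV outputs; determinism is a
  contract (repeated runs are byte-identical).
* Coincident centroids are detected with a 10⁻⁹ px tolerance.
* Rose diagrams bin on half-open sectors $[kw, (k+1)w)$ and are rendered
  as hand-generated SVG — plain text, no graphics device required — with
  the mean angle as a black radial line; wedge radius is proportional to
  count.
* PNG I/O uses the `png` package. TIFF has no available R reader in the
  target environment, so a minimal TIFF 6.0 subset codec is included:
  8-bit grayscale, uncompressed or LZW (with horizontal predictor), both
  byte orders, multi-strip; everything else is rejected with a message
  naming the preprocessing required. The LZW path is validated against a
  reference encoding produced by an independent implementation.
* Images whose values are already binary (`{0,1}` or `{0,255}`) pass
  through untouched; other 8-bit images threshold at a fixed cutoff or by
  Otsu's method (`"auto"`), since assuming a manual threshold would be
  wrong for a library.

## Known limitations

* Doublet splitting is axis-aligned and non-recursive by design.
* Compass cave criteria use image coordinates; if your anatomical axis is
  rotated relative to the frame, rotate the image first (as the original
  workflow does) or use `largest`.
* A cave centroid may fall outside the chunk for crescent-shaped caves;
  the measurement proceeds from centroids regardless, which is the
  defined behavior, not an error.
* The CLI batch mode applies one shared configuration to every image in
  the set.
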