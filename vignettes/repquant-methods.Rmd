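---
title: "Quantifying renal Epo-producing reporter cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying renal Epo-producing reporter cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repquant)
```

# The problem

Renal erythropoietin-producing (REP) cells are fibroblast-like interstitial
cells concentrated at the corticomedullary border of the kidney. Under
hypoxia a small subset of them transcribes Epo in short bursts; lineage
tracing tags these cells permanently with the red fluorophore tdTomato, and
whole kidney-slice fluorescence microscopy is then used to count them, map
their distribution across the renal compartments, extrapolate a per-kidney
total, test marker co-expression, and quantify per-cell Epo transcription by
single-molecule FISH. `repquant` implements that measurement chain as
reusable, tested code, together with a synthetic section generator that
provides exhaustive ground truth, so every stage can be benchmarked without
microscope data.

# Reporter-cell detection

The detection pipeline on the tdTomato channel is:

1. **8-bit conversion** — linear min–max rescale to 0..255, rounding half up.
   A constant channel maps to all zeros; the convention is arbitrary but
   fixed, and it makes "blank frame" a well-defined degenerate input rather
   than an error source.
2. **Background subtraction** — a median filter of half-width
   `backgroundRadius` (default 50 µm) estimates the slowly varying
   background, which is subtracted and clipped at zero. The estimator choice
   is ours: a median over a window several times the cell diameter flattens
   illumination gradients while passing 10–25 µm cells essentially
   untouched. The window is capped at half the frame for small images.
3. **Otsu binarization** — the threshold maximizes the between-class
   variance over all 255 splits of the 8-bit histogram; foreground is
   strictly above the threshold. Ties are broken towards the smallest
   maximizing level (relative tolerance 1e-9 on the variance), so the rule
   is deterministic even for symmetric histograms. A histogram with fewer
   than two populated bins has no separable classes; `detectCells` converts
   that into an empty result with a `noSignal` warning flag instead of
   failing, because blank slide regions are ordinary inputs.
4. **Connected components and the size filter** — components are labelled at
   8-connectivity (default; 4 is available) and those with an
   equivalent-circle diameter `2*sqrt(area/pi)` below 10 µm are discarded.
   The cutoff is inclusive and "diameter" is defined from the component area
   because the measurement is otherwise underspecified for irregular
   components. Touching cells count as one component and border components
   are kept — whole-slice images have slide background at their borders, not
   cropped tissue.

We apply background subtraction *before* thresholding: flattening after
binarization would have no effect on the mask, so this is the only order in
which both steps are meaningful.

The tissue area comes from the DAPI channel: Gaussian smoothing (σ = 10 µm),
Otsu, morphological closing with a 20 µm disk to merge the nuclear texture
into one region, retention of the largest component, and hole filling. Area
is reported in mm² as pixel count times `(pixelSize/1000)^2`.

Coordinates are 0-based `(row, col)` pixel indices; physical positions are
`index * pixelSize` µm. Component areas are reported in µm², tissue and zone
areas in mm².

# Zonation and whole-kidney extrapolation

Zone maps (cortex, OSOM, ISOM, IM, papilla, background) are **inputs**: in
real use they are curated label images drawn from the green tubular
autofluorescence, and the synthetic generator supplies procedurally defined
ones. Each detection is assigned the zone under its centroid pixel — plain
point counting; a majority vote over component pixels would change almost
nothing (cells are far smaller than zones) at real complexity cost.
Centroids on background become `unassigned`: excluded from per-zone
percentages but reported, so counts stay auditable.

Densities are `count/area` per zone; a zero-area zone yields an *undefined*
density with a flag, never a fabricated zero. For per-kidney totals, the
areal density is divided by the section thickness (12 µm cryosections by
default) to give a volumetric density, then multiplied by the ellipsoid
kidney volume `V = (π/6)·L·W·D`. No Abercrombie/over-projection correction
is applied — cells thicker than the section are over-counted — because the
published procedure applies none; this is a documented bias, not an
accident. When several slices are analyzed the package keeps per-slice
values and averages the per-slice estimates (mean), leaving other pooling
rules to the caller.

# Colocalization

Marker channels are binarized at fixed, experiment-level grayscale
thresholds supplied as configuration — deliberately not auto-thresholded,
since comparability across sections comes from keeping the threshold
constant. A detection is double-positive when its component pixel set
overlaps the marker mask by **at least 10 pixels**, inclusive. The rule is
kept in pixels rather than µm² to match its published definition exactly;
the recorded pixel size exposes the physical meaning (at 2 µm/px, 10 px =
40 µm²). Overlap is computed on the true component pixels, not a centroid
disk.

# FISH transcript quantification

Dot tables (manually annotated, CSV with `x_um, y_um`) are the canonical
input; `detectDots` provides an automated blob detector only so synthetic
end-to-end runs need no manual step, and it is excluded from benchmark
statistics. Dots are grouped into cells of origin by **single-linkage
clustering with an inclusive 5 µm radius**: two dots share a cell iff they
are connected by a chain of pairwise distances ≤ 5 µm. Single linkage is the
only linkage under which "dots forming clusters by proximity" is
well-defined through chaining; the implementation (hierarchical clustering
cut at the radius) is verified in the tests against a brute-force transitive
closure of the ≤ radius relation.

A FISH cell is co-labelled with the tdTomato lineage tag when its centroid
falls inside a detection's component, or failing that within 5 µm of a
detection centroid — mirroring how transcript clusters are visually assigned
to reporter-stained cells. Composition statistics report both directions
(percent of tagged cells that are FISH-positive, percent of FISH cells that
are tagged) with numerators and denominators; zero denominators yield
flagged undefined values.

Per-cell counts feed a Lorenz-type **contribution curve**: counts sorted
descending, cumulative cell fraction against cumulative transcript fraction.
With the descending sort the transcript fraction dominates the cell fraction
pointwise, with equality exactly for uniform counts. `contributorSlices`
reads the transcript share of any top cell fraction off the curve with
linear interpolation between ranks, which also resolves ties at the cutoff
rank. No attempt is made to guess published high/low-contributor boundaries:
cutoffs are explicit arguments.

# Washout kinetics

Carboxyhaemoglobin washout after CO exposure declines linearly towards a
baseline. `fitWashout` fits ordinary least squares to the points *above*
baseline (points at or below `baseline + baselineSd` are excluded — the
measured signal clamps there, and including them flattens the slope), and
requires at least three usable points and a negative slope. The half-life is
defined on the above-baseline saturation under the linear model: the time
for `S − baseline` to halve from its fitted t = 0 value,

$$t_{1/2} = \frac{S_0 - \text{baseline}}{2\,|\text{slope}|}.$$

A linear decline has no scale-free half-life, so this above-baseline
definition is the only one consistent with pairing "linear decline" with a
half-life. With `S0 = 54.8`, baseline `4.57` and slope `−0.7176` %/min this
gives 35.0 min. Fits are per-series; multi-animal summaries average
per-series half-lives.

# The synthetic generator

`syntheticSpec()` defaults define the study conditions the package is
benchmarked under; they are fixed, not tuned per run:

* **Frame**: 1024×1024 px at 2 µm/px (a ~2×2 mm field), elliptical tissue
  covering ~64% of the frame.
* **Zones**: concentric elliptical bands of the tissue ellipse, outermost =
  cortex, with radial-width fractions (0.35, 0.15, 0.20, 0.20, 0.10). Real
  zoning is manual and anatomical; a procedural stand-in is required for the
  truth to be exact.
* **Cells**: 300 per frame, concentrated at the corticomedullary border
  (45, 120, 75, 40, 20 across cortex→papilla), diameters uniform in
  12–20 µm (all above the 10 µm cutoff, so recovery is well-posed),
  intensity 200 over Gaussian noise of SD 8 (signal 25× noise; the
  recovery contract is stated down to 5× noise). Placement is rejection
  sampling on interstitial (non-tubule) pixels of the requested zone,
  forbidding overlap between cells, with bounded attempts and an explicit
  shortfall error — REP cells live exclusively in the peritubular
  interstitium, and non-overlap keeps one planted cell = one component.
* **Tubules**: random disks covering 30% of the tissue, rendered into the
  green autofluorescence channel.
* **Markers**: each cell is marker-positive with probability 0.25
  (Bernoulli), painted into the marker channel over the cell's own pixels;
  2% additional marker area is placed away from cells so specificity is
  exercised too.
* **FISH counts**: negative binomial with mean 5 and dispersion size 1.636.
  The family is our choice of over-dispersed ("burst-like") count model; the
  size was calibrated once, by solving the population Lorenz curve of
  NB(5, k), so that the top decile of cells carries 30% of transcripts —
  the degree of heterogeneity the analysis is designed around. Dots scatter
  around their cell with Gaussian jitter (SD 1.5 µm); in separable mode
  cells sit on a jittered grid with 25 µm spacing and jitter truncated at
  2.5 µm, which *guarantees* intra-cell dot spacing ≤ 5 µm and inter-cell
  nearest-dot spacing > 5 µm, so ground truth for the clustering stage is
  provable, not approximate.
* **Serial sections**: the extrapolation oracle plants 20,000 cells
  uniformly in a 3×2×1.5 mm ellipsoid and cuts six 12 µm sections within
  ±60% of the half-depth. The scaled-down geometry keeps rendered frames at
  ~1000×1500 px while leaving ~1200 detected cells across sections, enough
  for the 10% recovery contract; sections near the poles are avoided
  because their tiny cross-sections make single-section densities
  statistically meaningless.

All randomness in a generator call flows from the `SyntheticSpec`'s single
integer seed: the RNG is seeded once per operation and draws in a fixed order, so
identical specs give bitwise-identical outputs, and the caller's RNG state
is restored afterwards.

**What the generator does not emulate**: optical point-spread beyond dot
jitter, uneven illumination, autofluorescence bleed-through into the red
channel, touching or overlapping reporter cells, partial-volume effects at
section faces, irregular anatomical zone shapes, and tissue damage. Passing
the recovery benchmarks therefore demonstrates the correctness of the
measurement chain on data satisfying its stated assumptions — it does not
certify performance on real slides, where thresholding and the
no-cell-splitting rule are the fragile steps.

# Numerical choices and degenerate inputs

* Otsu ties → smallest maximizing threshold; variance compared with 1e-9
  relative tolerance.
* Constant channel → all-zero 8-bit image; single-bin histogram → "no
  separable classes", surfaced as an empty detection set with a warning
  flag.
* Background radius below 3 px is rejected (a median over fewer pixels is
  not a background estimate).
* Zero-area zones → undefined density with flag; zero denominators in
  composition statistics → flagged NA.
* All-zero count vectors are rejected by `contributionCurve` (no transcripts
  to apportion); cutoffs must lie in (0, 1].
* Washout fits refuse non-negative slopes and fewer than three
  above-baseline points.

# Known limitations

* Components are counted as single cells; touching tdTomato⁺ cells are not
  split (no watershed), matching the published counting rule.
* The extrapolation inherits the over-projection bias of uncorrected 2D
  counts.
* The FISH dot detector merges dots closer than about one pixel and is
  excluded from benchmark statistics by design.
* Marker thresholds are free configuration; nothing in the package validates
  their biological appropriateness.

# Benchmark sizes

The test suite and the acceptance script run the generator at the defaults
above: 10 seeds × 300 cells for detection/zonation recovery, 10 seeds × 400
cells for double-positive rates, one 20,000-cell ellipsoid with 6 sections
for extrapolation, 20 fields for contribution-share recovery, and
1000/500-case randomized oracle sweeps for the Otsu and clustering
equivalences. These sizes give binomial/sampling errors comfortably inside
each contract's tolerance while keeping a full run in the order of a minute.
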