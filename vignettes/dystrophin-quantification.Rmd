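---
title: "Quantifying sarcolemmal dystrophin: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcolemmal dystrophin: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysquant)
```

## The measurement problem

Duchenne muscular dystrophy (DMD) abolishes dystrophin expression; Becker
(BMD) and intermediate (IMD) phenotypes retain variable amounts of a
partially functional protein. Because dystrophin restoration is the endpoint
of several therapies, muscle biopsies must be scored for *how much*
dystrophin is present and *how it is distributed* along each fiber's
membrane. Visual scoring is operator-dependent; dysquant implements an
automated pipeline over two-channel immunofluorescence images of transverse
sections:

1. **laminin-α2** (channel `LAMA2`) outlines every fiber independently of
   disease status and is used as a *mask stain* to segment fiber instances;
2. **dystrophin** (channel `DYS`) is measured inside each fiber's
   sarcolemmal ring.

Per fiber the pipeline reports the mean ring intensity (AU on the 16-bit
acquisition scale, no background subtraction), the percentage of the
circumference with supra-threshold dystrophin ("coverage"), a positivity
call (coverage ≥ 25%), and one of four coverage bins
B1 = [0,25), B2 = [25,50), B3 = [50,75), B4 = [75,100]. Sections are
summarized as unweighted per-fiber means, percent positive fibers, bin
profiles and ECDFs; subjects are the mean ± sample SD of exactly two serial
replicate sections; phenotype groups are compared with exact Mann–Whitney U
tests on replicate-level values.

## Segmentation model

The laminin network is binarized (Otsu by default, or a fixed AU threshold);
fiber interiors are the connected components of the complement. Components
touching the image border are partial fiber profiles and are excluded;
components under `min_area` (default 100 px) are debris. Each interior then
grows back over its own laminin band (constrained, synchronous dilation), so
the fiber region includes the membrane the mask stain delineates — this is
what makes the subsequent inner band of the region coincide with the
sarcolemma. The sarcolemmal ring is the morphological inner band of
`ring_width` px (default 3); fibers too small to support the band keep their
whole region and are flagged.

Coverage is resolved by parameterizing ring pixels into `K` equal-angle arc
segments around the fiber centroid (default K = 360, i.e. 1°). An arc is
positive when its mean dystrophin value reaches the positivity threshold.
The default threshold is exposure-relative: the mode of the interstitial
(non-fiber) dystrophin pixels plus 3 scaled MADs, plus half an AU so that a
noiseless quantized background still separates strictly. A circular majority
filter of window `w = 3` suppresses single-segment flips — 1° flicker is
below optical resolution.

**Order of smoothing and interpolation.** At K = 360 many arc segments
contain no ring pixel (a 1° arc at a 20 px radius subtends well under one
pixel). Empty segments inherit the decision of the nearest measured segment.
The majority filter is applied *on the sequence of measured segments*, and
interpolation happens afterwards. The opposite order (interpolate, then
smooth) amplifies single-pixel noise: a background arc that noise pushes
above threshold gets copied into its empty neighbours and then survives the
majority filter. Because flips are one-directional (bright arcs sit many
noise SDs above threshold and essentially never flip down), that
amplification is a systematic upward coverage bias (~+2.7 points at default
noise in our measurements); smoothing in the measurement domain reduces it
to the ~+1.4 points attributable to optical smear at arc ends.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_area` | 100 | px | debris floor; fibers of interest are much larger |
| `ring_width` | 3 | px | sarcolemmal band ≈ 1.5 µm at 0.5 µm/px |
| `K` | 360 | arcs | 1° coverage resolution |
| `smoothing_w` | 3 | arcs | removes sub-resolution flicker |
| `laminin_threshold` | "auto" (Otsu) | AU | exposure-independent binarization |
| `positivity_threshold` | "auto" (mode + 3·MAD + 0.5) | AU | robust, exposure-relative; logged on every run |

The positivity threshold is the method's biggest free choice (the original
deployment buried it in a proprietary script); it is therefore configurable
as an absolute AU value for calibrated runs, and the resolved value is
always written to the run log.

## The synthetic-section generator

No biopsy images are public, so the simulator is a first-class module with
per-fiber ground truth. A section is a Lloyd-relaxed Voronoi mosaic of
Poisson-sampled seeds, eroded to leave an interstitial gap (default 3 px,
about the width of the endomysium at 0.5 µm/px) and a 4 px frame margin;
each surviving cell becomes a convex fiber polygon. Per fiber, the phenotype
preset supplies ground truth hierarchically: a coverage bin from the
preset's bin fractions, uniform coverage within the bin, and a lognormal
intensity with the preset's arithmetic mean and CV, censored to [0, 65535].
The positive dystrophin arc is one contiguous angular run at a random phase
— published section images show contiguous partial rings, though their arc
topology is not quantified; contiguous is the simplest testable convention.
Rendering draws the laminin ring along every boundary and the dystrophin
signal on the arc, then applies Gaussian optical blur (σ = 0.8 px), additive
Gaussian sensor noise and 16-bit quantization.

Preset compositions are the published group profiles: controls ~100% of
fibers in B4 at ~50,387 AU; DMD 52/30/12/6% across B1–B4 at ~11,947 AU; mild
BMD ~85% in B4 at ~28,477 AU; two severe-BMD patterns bracketing the
mild-like (98% B4, 30,798 AU) and DMD-like (19/24/27/32 normalized,
13,657 AU) extremes; IMD follows its majority pattern (86% B4, 18,319 AU).
The per-fiber intensity CV (0.2) is not printed anywhere and was chosen once
as a realistic within-section spread consistent with the published
cumulative-frequency curves; the default noise SD (2,519 AU) puts the
control preset at SNR ≈ 20, clean enough that segmentation error does not
dominate recovery tests.

What the generator does **not** emulate: regenerating or necrotic fibers,
oblique (non-transverse) profiles, freezing artefacts, autofluorescence,
channel bleed-through, scanner tile seams, or scattered (non-contiguous)
dystrophin arcs. A green recovery test therefore establishes that the
measurement chain is unbiased on clean transverse geometry at realistic
noise — not that it is robust to every histological artefact. Fiber scale in
tests (radius ~20 px) is a scaled-down analogue of real sections to keep
runtimes reasonable; the geometry-dependent steps are resolution-relative.

## Statistics

The exact Mann–Whitney two-sided p is `2 * P(U <= min(Ux, Uy))` under the
permutation null, computed by the standard counting recurrence, with a full
enumeration oracle and closed forms (`2 / choose(n1+n2, n1)` at complete
separation) as independent checks in the test suite. Ties or pooled sizes
over 30 fall back to a midrank, tie-corrected normal approximation with
continuity correction, and the result is flagged. Statistics are computed on
replicate-level values (two per subject): it is the only reading under which
the published small-cohort p-values (0.0095 = 2/C(10,4), 0.0286 = 2/C(8,4),
0.0011 = 2/C(16,4), 0.0022 = 2/C(12,6)) are achievable, so it is adopted and
documented. No multiple-testing correction is applied by default, matching
the unadjusted pairwise reporting convention at α = 0.05.

With exactly two replicates, a subject's published mean m and sample SD s
determine the replicate pair as m ± s/√2 (`replicates_from_mean_sd()`),
which is how cohort-table inputs can be carried back to the replicate level.

Pearson correlation between image metrics and Western-blot percent of
control is computed directly from sums of squares. Note the published
correlation figures are internally inconsistent (two different values are
printed for the same panel), so the package verifies its correlation against
direct computation on the published table (r ≈ 0.91 for WB vs intensity)
rather than against a printed coefficient.

## Numerical conventions and degenerate inputs

* Pixel coordinates are pixel-centred, origin top-left, (row, col), ranges
  half-open; images are integer matrices in [0, 65535].
* Bin edges are half-open with 25/50/75 belonging to the upper bin, which
  reconciles the two inconsistent bin labelings and positivity phrasings in
  the source material into one rule: positive ⇔ coverage ≥ 25 ⇔ not B1.
* Mean ring intensity is the ring-pixel mean over the *full* ring (not only
  positive arcs), raw AU.
* Flat or empty laminin images raise "no fibers segmented"; empty record
  lists, empty groups, zero variance and out-of-range coverages are errors,
  not silent NAs. Intensity overflow after noise is clipped at 65535, not an
  error.
* All randomness flows through explicit seed arguments; no global RNG state
  is consumed or perturbed.

## Known limitations

* The connected-component strategy assumes the laminin network separates
  adjacent fibers; extremely thin or broken walls would merge instances (the
  simulator guarantees a gap; real sections may not).
* Non-convex fibers are parameterized by centroid angle; for strongly
  non-convex profiles arc segments can interleave.
* Coverage carries a small positive bias (~1–2 points) from optical smear at
  arc ends; it is visible in the recovery tests and bounded by their
  tolerances.
* The Western-blot module starts from band-intensity tables; gel-image
  densitometry is out of scope.
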