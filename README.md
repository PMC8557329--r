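# dysquant

Operator-independent quantification of dystrophin expression in two-channel
immunofluorescence images of transverse skeletal-muscle sections.

Dystrophin loss causes Duchenne muscular dystrophy (DMD); partial expression
gives the milder Becker (BMD) and intermediate (IMD) phenotypes, and
dystrophin *restoration* is the endpoint of several therapies. Assessing a
biopsy therefore requires both **how much** dystrophin a fiber expresses and
**how it is distributed** along the fiber membrane. dysquant implements a
high-throughput image-analysis pipeline for this:

* **Segmentation** — laminin-α2 is a disease-independent *mask stain*; the
  binarized laminin network (Otsu) defines myofiber instances as connected
  components of its complement, excluding border-touching partial profiles,
  and each fiber's sarcolemmal ring is extracted as a morphological inner
  band.
* **Per-fiber metrics** — mean dystrophin intensity over the ring (AU on the
  16-bit scale), circumference coverage (% of K = 360 one-degree arc
  segments above a robust background threshold), positivity
  (coverage ≥ 25 %) and coverage bins B1 [0,25), B2 [25,50), B3 [50,75),
  B4 [75,100].
* **Aggregation** — section summaries (mean intensity, % positive fibers,
  bin profiles, ECDFs), subject records (mean ± SD over exactly two serial
  replicate sections), and phenotype-group comparisons.
* **Statistics** — exact Mann–Whitney U (two-sided
  p = 2·P(U ≤ u_min), counting recurrence; at complete separation
  p = 2/C(n1+n2, n1)) on replicate-level values; Pearson correlation against
  Western blot.
* **Western blot** — dystrophin band intensity normalized to the α-actinin
  loading control, percent of control, mean ± SD over 4 technical repeats.
* **Simulator** — synthetic two-channel sections with per-fiber ground truth
  (Lloyd-relaxed Voronoi fiber mosaics; phenotype presets reproducing
  published group profiles, e.g. controls ≈100 % of fibers at 75–100 %
  coverage at ~50,387 AU, DMD ≈52/30/12/6 % across bins at ~11,947 AU),
  used throughout the tests as ground truth.

## Worked example

```r
library(dysquant)

# a synthetic DMD-like section with ground truth, then the full pipeline
sim <- simulate_section("DMD", 300, render_config(image_size = 512), seed = 42)
q   <- run_quantify(sim$image)
q$summary
#> <section_summary> 287 fibers | mean intensity 3957 AU | 48.4% positive
#>   bin fractions: B1=0.516 B2=0.279 B3=0.122 B4=0.084

head(q$records[, c("fiber_id", "mean_intensity_au", "coverage_pct", "bin")], 3)
#>   fiber_id mean_intensity_au coverage_pct bin
#> 1        1          2772.924     28.61111  B2
#> 2        2          3142.394     21.94444  B1
#> 3        3          2864.110     28.33333  B2
```

287 of 300 rendered fibers survive the border/debris filters; 48.4 %
positive and the B1–B4 split of 52/28/12/8 % recover the DMD preset
(52/30/12/6 % of fibers, i.e. about half the fibers dystrophin-negative).
The full-ring mean intensity (~4,000 AU here) is much lower than the preset
arc intensity (11,947 AU) because negative arcs contribute background — the
ring mean is deliberately computed over the whole sarcolemma.

Cohort comparison on replicate-level values (2 sections/subject): two
controls versus three mild-BMD subjects with completely separated
intensities give the minimal exact p:

```r
exact_mann_whitney(c(51234, 49870, 50211, 50904),
                   c(12110, 11873, 12493, 11410, 12001, 11646))
#> <group_comparison> n1 = 4, n2 = 6, U = 24.0, two-sided p = 0.009524 (exact)
```

Section images travel as uncompressed 16-bit multi-page TIFF
(`write_section_tiff()` / `read_section_tiff()`, channels "DYS"/"LAMA2");
`run_quantify()` and `run_cohort()` write CSV outputs plus the resolved JSON
config and a provenance log. A command-line front end with subcommands
`simulate / quantify / summarize / compare / wb` is in
`inst/cli/dysquant.R`.

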