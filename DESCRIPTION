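Package: dysquant
Title: Operator-Independent Dystrophin Quantification in Muscle Sections
Version: 0.1.0
Authors@R: person("dysquant", "maintainers", email = "dev@example.org",
    role = c("aut", "cre"))
Description: High-throughput quantification of dystrophin expression in
    two-channel immunofluorescence images of transverse skeletal-muscle
    sections. Segments myofiber instances from the laminin-alpha-2 mask
    stain, measures per-fiber sarcolemmal mean intensity and circumference
    coverage, classifies dystrophin-positive fibers and coverage bins,
    aggregates sections and replicate pairs into subject summaries, and
    compares phenotype groups with exact Mann-Whitney U tests. Includes a
    synthetic two-channel section simulator with per-fiber ground truth and
    a Western-blot normalization module.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
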