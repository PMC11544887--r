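Package: tumortract
Title: Tumor-Associated Diffusion MRI Tractography and Downstream Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for tumor-associated tractography in glioblastoma:
    multi-tensor diffusion-weighted phantom simulation, q-space orientation
    reconstruction with quantitative anisotropy, diffusion tensor scalar maps
    (FA/MD/AD), deterministic streamline tracking by Euler integration over a
    tri-linearly interpolated peak field, tumor-ROI tract selection with
    core/shell/projecting classification and bundle counting, quartile-stratified
    Kaplan-Meier survival statistics, and a voom-based differential expression
    stage with exact over-representation testing. Synthetic phantoms, survival
    cohorts and count matrices make every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    limma,
    edgeR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
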