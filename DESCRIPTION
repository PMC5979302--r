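Package: ampliCNV
Title: Copy-Number Screening for Dual-Gene Targeted Amplicon Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for copy-number-variant (CNV) screening on dual-gene
    multiplex amplicon panels such as BRCA1/BRCA2 diagnostic kits.
    Processes capillary-electrophoresis fragment-analysis traces
    (peak detection, size-standard calibration, amplicon assignment),
    performs cross-gene peak-height normalization against a confirmed
    copy-number-normal reference, computes per-amplicon read-count
    frequencies with run-level 99% confidence intervals and global
    gene-ratio statistics, integrates both evidence streams into
    per-amplicon and gene-level CNV calls that expose the whole-gene
    deletion/duplication ambiguity inherent to intra-sample
    normalization, and resolves that ambiguity with MLPA/MAQ-style
    dosage quotients.  A synthetic-data module generates traces,
    read-count matrices and dosage runs under arbitrary copy-number
    states, and a command-line interface chains the stages into a
    screening pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
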