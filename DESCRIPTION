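Package: mirpipe
Title: Small RNA-Seq MicroRNA Profiling of Megakaryocyte-Derived
    Microparticles and Related Cell Populations
Version: 0.1.0
Authors@R:
    person("mirpipe", "developers", email = "mirpipe@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for profiling microRNA cargo in
    small RNA sequencing libraries from megakaryocytes (Mk), megakaryocytic
    microparticles (MkMP), platelet-like particles (PLP) and platelets
    (PLT). Implements 3' adapter detection with mandatory retention,
    quality end-trimming to a mean Phred threshold, size-fraction
    partitioning, identical-sequence clustering, assignment to a collapsed
    mature microRNA reference, counts-per-million normalisation, a
    negative-binomial exact test with common dispersion and
    Benjamini-Hochberg FDR for two-group enrichment, and
    detection/abundance/composition/Venn reporting. Ships a synthetic
    library generator with full ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
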