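Package: telonick
Title: Single-Molecule Nick-Map Analysis of Subtelomeres and Telomere Length
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for nanochannel optical genome mapping of
    human subtelomeres: in-silico nicking endonuclease digestion of reference
    sequences (Nt.BspQI-style motifs), simulation of nick-labeled single DNA
    molecules with realistic label error models, dynamic-programming
    alignment of molecule label patterns to reference nick maps,
    reference-anchored consensus map construction with end extension,
    haplotype partitioning and large structural-variant calling, and
    single-molecule telomere length estimation with per-telomere and
    per-haplotype summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
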