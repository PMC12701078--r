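Package: evmirna
Title: Paired Analysis of Extracellular-Vesicle miRNA qPCR Array Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for circulating extracellular-vesicle
    (EV) miRNA profiles measured on 384-assay qPCR arrays around a paired
    intervention: limit-of-detection imputation of "undetermined" CT values,
    detection-based assay filtering, spike-in (cel-miR-39) delta-CT
    normalization to log2-scale expression, paired differential expression
    with Benjamini-Hochberg FDR control and per-patient directional
    consistency calls, miRNA-target-derived preranked gene-set enrichment
    analysis (weighted running-sum enrichment score, gene-label permutation
    null, NES, tail-wise FDR, leading edge), and construction of the
    thresholded tripartite miRNA-gene-pathway network. A seeded simulator
    generates paired pre/post CT matrices with censoring at the limit of
    detection, target maps and gene-set collections, so every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
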