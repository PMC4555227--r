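Package: etscre
Title: Cooperative GABPa-CREB1 Binding Analysis for ETS-CRE Protein Binding Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing custom protein binding
    microarrays (PBMs) that probe cooperative binding of the ETS-domain
    monomer GABPa and the B-ZIP dimer CREB1 to overlapping ETS and CRE
    motifs (the composite ETS-CRE 16-mer). Includes combinatorial probe
    enumeration for the 177,440-feature array design, a synthetic spot
    intensity generator with programmed affinity and cooperativity
    effects, replicate aggregation and cross-condition normalisation,
    SNP fold-change and cooperativity-ratio analytics, construction of
    position weight/frequency matrices from SNP-panel median intensities
    with BEEML-style energy scoring, genome-wide motif enrichment in
    ChIP peak groups, and an FDR-controlled caller for cooperatively
    bound loci based on dinucleotide-preserving shuffled decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    matrixStats,
    withr,
    yaml,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
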