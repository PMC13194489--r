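Package: geoadapt
Title: Comparative Genomics and Phenotyping of Anode-Adapted Geobacter Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing laboratory-evolved bacterial lineages
    from resequencing, structural modelling, qRT-PCR and growth data. Includes
    a synthetic-data generator that plants known mutation spectra (Ts/Tv,
    dN/dS, loss-of-function rates, mutational hotspots, deletions) into an
    annotated genome; codon-level variant effect annotation; genome-wide
    mutation statistics (transition/transversion ratio, Nei-Gojobori dN/dS,
    hotspot detection, genome-reduction and alignment-gap metrics); rigid-body
    protein superposition with TM-score and secondary-structure comparison;
    relative expression by the 2^-ddCt method; and exponential growth-rate
    estimation with strain contrasts. All results are tibbles designed for
    piped workflows, with broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    BiocGenerics,
    bio3d,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
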