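Package: proteomap
Title: Physicochemical Profiling and Virtual 2D Maps of Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Per-protein physicochemical profiling of multi-FASTA proteomes:
    amino-acid composition, average molecular weight, and isoelectric point
    computed from a Henderson-Hasselbalch charge model with selectable pKa
    sets.  Profiles aggregate into host-group and kingdom-level summaries
    (mean length, molecular weight, isoelectric point, acidic/neutral/basic
    partition, extreme records), feed Pearson correlation and NIPALS
    principal-component analysis of composition matrices, and render as
    virtual two-dimensional (isoelectric point by molecular weight) proteome
    maps whose unimodal/bimodal/trimodal structure is called by a
    kernel-density peak classifier with topographic prominence filtering.
    A synthetic-proteome generator with controllable length distributions,
    residue-frequency profiles, and charge-mode structure provides ground
    truth for every stage.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
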