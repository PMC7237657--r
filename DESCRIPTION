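Package: imprintloop
Title: Chromatin Looping, Allele Specificity and 3D FISH Colocalization at
    Imprinted Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chromosome conformation capture (3C) studies
    of imprinted regions such as human 11p15.5. Provides in-silico restriction
    digestion and fragment-axis construction, normalization of 3C band
    intensities against an equimolar control template into interaction
    frequencies, differential interactome calling between control and patient
    cell lines (two-way ANOVA with Bonferroni per-fragment contrasts and
    classification of regions of interaction as unchanged, increased,
    decreased, novel or lost), allele-specificity calling of ligation products
    from SNP signals, imprinting-control-region methylation status
    classification, and two-colour 3D DNA FISH analysis (doublet pairing,
    cis-colocalization and trans-association classification, nucleus
    categories, cohort summaries, Fisher and t statistics). A synthetic-data
    generator reproduces the statistical structure of every input so the whole
    pipeline is testable without microscope or gel data.
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
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
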