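Package: telorearr
Title: Telomere and Subtelomere Rearrangement Analysis for Yeast Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation of telomeres, subtelomeric X and Y' elements on
    telomere-to-telomere assemblies of Saccharomyces cerevisiae, homopolymer-
    condensed Y' variant cataloguing and clustering, control-versus-survivor
    rearrangement calling (Y' losses, gains, tandem amplifications, mosaic
    variants, terminal duplications, chromosome circularization), detection of
    rolling-circle (t-circle) amplification signatures in elongated telomeres,
    and telomere length distributions from assemblies and long reads. Includes
    a synthetic-genome generator with a planted-truth ledger so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
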