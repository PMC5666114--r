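Package: openring
Title: Rigid-Body SAXS Refinement of Helical and Ring Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the solution geometry of symmetric protein
    oligomers from small-angle X-ray scattering (SAXS) data. Builds helical
    segments and closed rings from a rigid seed unit by repeated application of
    one rigid transformation, computes theoretical scattering profiles with the
    Debye formula, and refines the inter-unit transformation by grid search and
    local descent against an experimental profile using reduced chi-square with
    an analytic scale factor. Includes rigid-body geometry utilities (Kabsch
    superposition, Euler-angle and screw-parameter extraction, twist-swing
    rotation decomposition), steric-clash based assembly termination analysis,
    Shrake-Rupley buried interface areas, majority-rule consensus sequence
    design from redundancy-filtered alignments, and a synthetic-data module
    that generates bead models, ground-truth assemblies, noisy profiles and
    alignments so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
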