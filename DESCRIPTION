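Package: trabqtl
Title: Trabecular Bone Morphometry and Consomic QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic dissection of trabecular bone structure
    with chromosome-substitution (consomic) mouse panels.  Computes the six
    standard micro-CT morphometric parameters (BV/TV, Tb.N, Conn.D, Tb.Sp,
    SMI, Tb.Th) from binary voxel volumes, including an Euler-characteristic
    connectivity density, sphere-fitting local thickness, and a
    surface-dilation structure model index; screens consomic panels against
    the host strain with Dunnett's many-to-one test, Spearman trait
    correlations and a nonadditivity (epistasis) index; and maps QTL on
    subconsomic panels by similarity ordering, breakpoint block partition,
    Welch neighbor tests and block-level QTL assignment.  Includes synthetic
    phantom and panel generators with analytic ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    mvtnorm,
    jsonlite,
    readr,
    tiff,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
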