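Package: rarebin
Title: Multi-Bin Rarefying for Alpha Diversity Analysis of Immune Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and association testing of alpha diversity in T-cell
    receptor (TCR) repertoire sequencing data whose library sizes span orders
    of magnitude. Samples are partitioned into sequencing-depth bins, rarefied
    (subsampled without replacement) to the lower bound of their own bin,
    tested for phenotype association within each bin by linear regression, and
    pooled across bins by fixed-effect meta-analysis with a Wald test under
    equal, sample-size, or inverse-variance weights. Also provides the usual
    normalization baselines (no rarefying, overall rarefying, LOESS
    residualization), depth diagnostics, and a simulation framework for
    assessing type-I error and power under library-size confounding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vegan,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
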