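Package: leptodiet
Title: Metabarcoding Diet Analysis and Prey-Field Bioenergetics for Eel Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for DNA-metabarcoding gut-content
    studies of fish larvae, built around the diet of European eel (Anguilla
    anguilla) leptocephali in the Sargasso Sea. Provides a synthetic-data
    generator (reference database, Dirichlet-multinomial gut and marine-snow
    communities, host-contaminated amplicon reads, larval length cohorts and
    depth-stratified Hydrozoa fields), greedy OTU clustering with explicit
    read- and sample-level filtering rules, best-hit taxonomy assignment with
    lowest-common-ancestor resolution of ties, median-of-ratios normalization
    with PCA and a multivariate negative-binomial permutation test,
    depth-integrated zooplankton carbon biomass, and a prey-encounter
    bioenergetic sufficiency model for leptocephali feeding on siphonophores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
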