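Package: homomer
Title: Protein Homo-Oligomer Distributions, Power-Law Fits and the
    Resource-Precision Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the distribution of protein
    homo-oligomerization degree across proteomes. Computes subunit-number
    frequency distributions (whole proteome, parity subsets, category- and
    pathway-stratified, abundance-weighted), fits discrete power laws to
    protein-protein interaction degree data by zeta-normalized maximum
    likelihood with Kolmogorov-Smirnov k_min selection and bootstrap
    goodness-of-fit, fits log-log least-squares power laws to small
    frequency tables, and implements a resource-precision model in which
    the frequency of k-subunit homo-oligomers scales as k/2^k together
    with the derived information-capacity statistic c(k) = f_s(k) * k.
    Includes a synthetic proteome and interaction-network generator so the
    full analysis is testable without external downloads, readers for
    UniProt-style subunit annotation tables and STRING-style edge lists,
    and an end-to-end pipeline with reproducible seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    igraph,
    yaml,
    optparse
Config/testthat/edition: 3
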