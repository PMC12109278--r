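Package: dnatopo
Title: Topology of DNA Replication Intermediates from Coarse-Grained
    Conformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the topological analysis of circular DNA and
    partially replicated intermediates represented as coarse-grained 3D
    conformations.  Computes Gauss linking integrals between piecewise
    linear strand curves, per-segment-pair contribution matrices, twist,
    writhe and the five-component decomposition of the linking number
    difference in replication intermediates (unreplicated twist and
    writhe, parental-daughter wrapping, precatenanes, and plectonemes of
    precatenanes).  Detects juxtaposition (collision) events on reduced
    midpoint curves, classifies them into four types and assigns the
    chirality and topological sign of each crossing.  Includes a seeded
    generator of circular duplexes, supercoiled plectonemes and
    replication intermediates with prescribed topology, a
    topology-preserving Monte Carlo relaxer, and readers and writers for
    oxDNA-style topology/configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
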