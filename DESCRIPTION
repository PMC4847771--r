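Package: swarmsig
Title: Evolution of Signal-Based Swarming in 3D Foraging Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulator of foraging agents in a toroidal 3D arena
    whose recurrent (Elman-style) neural controllers are evolved by an
    asynchronous steady-state genetic algorithm.  Agents cannot sense the
    resource they depend on; their only input is directional signaling from
    neighbours, from which collective motion can evolve.  The package provides
    the full simulation engine (energy ledger, reproduction, population
    homeostat, resource relocation, signal silencing and freerider injection
    protocols) together with the analysis toolkit used to characterise runs:
    neighbourhood statistics, plug-in entropy / mutual-information / transfer
    entropy estimators and neighbourhood transfer entropy (leadership
    inference), genotypic Shannon diversity, distance-to-goal statistics,
    controller response surfaces, PCA embedding of genotypes, and lineage
    tracking with Newick phylogeny export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
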