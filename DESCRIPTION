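Package: dactynet
Title: Habitat Structure in Orchid Mycorrhizal Communities and Bipartite Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of orchid mycorrhizal OTU tables: rare-OTU and
    mycorrhizal-family filtering, species-level community ordination (NMDS)
    and permutational multivariate analysis of variance, bipartite
    orchid-fungus network modularity with simulated-annealing module
    detection and degree-preserving null models, and indicator-species
    (IndVal) analysis over habitats and habitat combinations. Includes a
    synthetic community generator with planted habitat modules for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vegan,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
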