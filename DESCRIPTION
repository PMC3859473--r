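Package: zoometapop
Title: Representation and Metapopulation Clustering of Threatened Species in Zoo Networks
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse how threatened terrestrial vertebrates are held
    across a global zoo network. Provides a resampling test (with an exact
    hypergeometric engine) of whether each taxonomic order holds more or fewer
    IUCN Red List threatened species than expected under random collection,
    and a Monte Carlo spatial analysis that finds, for each taxonomic class,
    the radial distance between zoos at which the probability of assembling a
    threshold metapopulation (50, 100 or 250 individuals) is highest relative
    to that distance. A synthetic-data generator emulates the structure of a
    global zoo information network (spatially clustered zoos, heavy-tailed
    abundances, tunable collection bias) so every analysis can be exercised
    without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
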