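Package: sparesim
Title: Simulating Land Sharing, Land Sparing and Three-Compartment
    Sparing Conservation Policies on Gridded Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A scenario simulator for agri-environmental conservation
    policy on gridded agricultural landscapes.  Three strategies (area-
    targeted land Sharing, output-neutral land Sparing, and Three-
    Compartment Sparing that splits spared land between natural habitat
    and very low-yield agriculture) are each implemented under three
    allocation rules (equal allocation, cost minimization, biodiversity
    maximization) and two conservation habitats (semi-natural grassland,
    broadleaf woodland).  Outcomes are scored by a Gain-in-Occupancy
    biodiversity metric summed over cells and species and averaged over a
    climate-forced horizon, by food-output change and its leakage
    implications, and by discounted opportunity cost.  A seeded synthetic
    landscape generator provides spatially autocorrelated yields with a
    low-yield upland stratum and heterogeneous species responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
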