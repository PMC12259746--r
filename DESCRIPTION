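Package: habnet
Title: Graph-Based Habitat Connectivity and Fragmentation Analysis on
    Land-Cover Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-epoch ecological-connectivity pipeline for categorical
    land-cover rasters: resistance (friction) surfaces from a land-cover
    resistance table plus buffered linear infrastructure, habitat-patch
    delineation with a minimum-area rule, least-cost effective distances and
    corridor polylines over the resistance surface, a dispersal-thresholded
    habitat graph, graph connectivity metrics (betweenness centrality, the
    integral index of connectivity IIC, the probability of connectivity PC,
    and equivalent connectivity EC), fragmentation indices (splitting index,
    effective mesh size, edge length and edge density), confusion-matrix
    accuracy assessment with Cohen's kappa, and an occurrence-record
    distance-to-network analysis with a seeded random-point null. Includes a
    seeded synthetic-landscape generator so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
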