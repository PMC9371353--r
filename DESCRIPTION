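Package: ndmscan
Title: Network Diffusion Modelling and Seed-Region Scanning on Brain Connectomes
Version: 0.1.0
Authors@R: person("NDM", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates trans-network spread of neurodegenerative pathology on
    weighted structural connectomes using the linear network diffusion model
    (heat kernel of the symmetric normalized graph Laplacian), computes
    regional atrophy maps (t-statistics) from subject-level volumetric tables,
    scans all bilateral seed pairs to rank candidate disease epicentres by the
    maximum seed-excluded Pearson correlation between predicted and measured
    atrophy over model time, and tests the best correlation against
    degree/strength-preserving randomized null connectomes. Includes a
    synthetic-data generator with a planted diffusion seed so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
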