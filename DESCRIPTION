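Package: sdmconsensus
Title: Consensus and Uncertainty Mapping for Species Distribution Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines heterogeneous continuous habitat-suitability predictions
    into consensus and uncertainty maps for two timeframes. Each model surface
    is binarized with a fixed-omission (presence percentile) threshold
    calibrated on species occurrence records, harmonized onto a common
    equal-area grid of square cells, and summed into per-cell inter-model
    agreement. Agreement is classified into three categories (unsuitable with
    low uncertainty, high uncertainty, suitable with low uncertainty), crossed
    across timeframes into nine change trajectories with a traffic-light
    palette, and summarized over urban-area polygons with a precautionary
    worst-case override. Includes a seeded synthetic-data generator (Gaussian
    random fields, biased occurrence sampling, zone polygons) so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
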