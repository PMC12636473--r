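Package: bgconnect
Title: Connectomic Analysis of Basal Ganglia Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dense synaptic-resolution connectomes of the
    songbird basal ganglia (Area X) and similar circuits. Provides a tabular
    connectome data model with SWC skeletons, quality-control filters for
    synapses and cell completeness, per-cell skeleton morphometry with
    threshold-based interneuron classification, cell-type connectivity
    matrices under three normalizations, a permutation null model for the
    pallidal target selectivity of striatal projection neurons, directed
    reciprocity statistics, and a synthetic-connectome generator with
    exported ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
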