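Package: voxconn
Title: Voxel-Wise Functional Connectome Construction and Graph Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary correlation networks from voxel-wise (or generic
    node-wise) biological time series and computes a full graph-theoretic
    battery on them: blocked Floyd-Warshall and multi-source BFS all-pairs
    shortest paths, clustering and characteristic path length, Newman
    spectral modularity via an implicit modularity-matrix operator and a
    division queue, Maslov-Sneppen degree-preserving null ensembles,
    small-world indices, power-law degree fits and hub detection. Includes
    analytic sparsity bounds (average-degree lower bound, Bonferroni-corrected
    correlation threshold), NIfTI and Matrix Market input/output, a planted
    modular synthetic-data generator for offline testing, and an end-to-end
    threshold-sweep pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
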