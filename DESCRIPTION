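Package: misrank
Title: Gene-Set Association and Disease-Class Ranking on Weighted
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the association between a query gene set and many
    disease-gene classes on a weighted protein-protein interaction network.
    Each disease gene receives its maximum interaction score (MIS) against
    the query set, calibrated by a permutation test over randomly sampled
    gene sets to yield an empirical p-value; per-class p-value distributions
    are summarised by proportion-threshold (PT) curves and their exact area
    under the curve (AUC), which ranks the classes. Includes readers for the
    STRING protein.links edge-list dialect, gene-set and class-catalog files,
    a synthetic study generator with planted association signal for
    benchmarking, and a single-call study driver that writes all result
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
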