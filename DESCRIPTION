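Package: repelsim
Title: Agent-Based Simulation of Cell Segregation and Border Sharpening
    by Contact Repulsion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Off-lattice agent-based model of cell segregation and tissue
    border sharpening driven by contact inhibition of locomotion. Cells are
    deformable rings of eight membrane nodes with a leader node that sets the
    migration direction; adhesion is modelled as stochastic links between
    membrane nodes of touching cells, and repulsion as a probabilistic,
    directed reassignment of the leader to the node opposite a broken link.
    The package converts measured cell behaviour (contact durations and
    collapse frequencies) into simulation probabilities, ships a preset
    catalog for EphB2/ephrinB1-type co-culture conditions, implements the
    quantitation algorithms used for such assays (nearest-heterotypic-
    neighbour border length, particle-analysis clustering, contact-event
    statistics, repulsion ratios), and runs replicated in-silico segregation
    and boundary assays with nonparametric across-condition comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, yaml, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
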