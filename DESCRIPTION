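Package: boolsym
Title: Dynamical Reflection Symmetry and Long Cycles in Signed Threshold Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying long limit cycles and dynamical reflection
    symmetry in synchronous signed threshold Boolean networks. Provides the
    threshold update rule and exhaustive state-transition maps, linear-time
    attractor and basin detection, exact and Monte-Carlo reflection-symmetry
    metrics (fully symmetric transition fraction and the partial symmetry
    ratio), a census of 3-node signed motifs with suppressed-motif detection
    and motif-gluing network construction, a non-dominated-sorting Pareto
    genetic algorithm trading off cycle length against edge count, random
    network ensembles (uniform trit, fixed-density, Kauffman NK) with
    sampling surveys, and readers/writers for TSV/JSON matrices and the
    BoolNet '.bnet' model format, plus a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
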