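Package: tlgrn
Title: Time-Lagged Information-Theoretic Gene Regulatory Network Inference
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers gene regulatory networks from equally spaced time-series
    expression data using time-lagged information theory. Provides binary
    quantization of expression profiles, a non-negative pairwise regulatory
    time-lag estimator, time-lagged mutual information (TLMI) and time-lagged
    conditional mutual information (TLCMI), and network inference by minimum
    description length (network MDL) and predictive minimum description length
    (PMDL) threshold selection with conditional-mutual-information pruning of
    indirect edges. Includes a synchronous Boolean-network simulator for
    generating benchmark time courses, precision/recall evaluation against a
    reference network, and data-size sweep utilities for studying the
    saturation of mutual information with increasing numbers of time points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
biocViews: NetworkInference, GeneExpression, TimeCourse, SystemsBiology
RoxygenNote: 7.3.3
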