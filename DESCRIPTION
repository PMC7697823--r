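Package: pathminer
Title: Clinical Pathway Mining and Attention-Based Outcome Prediction for Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw electronic-health-record event tables into
    per-patient or per-admission event sequences, mining closed frequent
    sequential patterns as candidate clinical pathways, selecting and labeling
    patient cohorts by pathway containment, training an attention-augmented
    LSTM outcome classifier on day-bucketed feature tensors, and exporting
    attention heat-map, treemap, and Sankey pathway-graph payloads for
    downstream visualization. Includes a synthetic EHR generator with planted
    pathways and a known outcome mechanism so the whole pipeline can be
    exercised and validated without access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
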