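Package: linkbench
Title: Benchmarking Record-Linkage Algorithms on Paired EHR Identifier Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for comparing record-linkage algorithm families on
    paired inpatient/outpatient identifier datasets. Implements a synthetic
    generator for corruptible patient identifiers with a hidden ground truth
    and an alloyed medical-record-number gold standard; preprocessing and
    deduplication; DOB/YOB blocking; exact and Jaro-Winkler field comparison;
    Fellegi-Sunter, expectation-maximization, EpiLink, and deterministic
    weighting across a 17-run dialect matrix; weight scaling, dense ranking,
    and two ensemble combiners; and evaluation against the gold standard
    (confusion metrics at rank thresholds, ROC/AUC, weight correlations, PCA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
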