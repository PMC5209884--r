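Package: bayesdx
Title: Instance Graphs and Estimation for Bayesian Diagnostic Test Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents diagnostic test accuracy studies as typed instance
    graphs of tests, test executions, samples, dispositions and estimates;
    estimates sensitivity, specificity, predictive values and prevalence
    from 2x2 contingency tables with Wilson or Clopper-Pearson confidence
    intervals; derives predictive values from prevalence, sensitivity and
    specificity via Bayes' equations; pools estimates after checking
    compatibility of index-test, reference-test and population hierarchies;
    simulates heterogeneous populations exhibiting the spectrum effect and
    quantifies how sample proportions approximate population quantities;
    and serializes instance graphs to a restricted Turtle vocabulary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
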