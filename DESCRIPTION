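Package: fragindex
Title: Somatic Repeat Instability Indices from Fragment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of somatic short-tandem-repeat instability from
    capillary-electrophoresis fragment analysis. Reads peak tables and raw
    traces, calls and bins electropherogram peaks to integer repeat counts,
    computes signed somatic instability indices (with expansion and
    contraction decompositions) under a signal-to-noise threshold, compares
    microsatellite loci against a reference sample, and provides the
    group-level statistics used in repeat-expansion studies (one-way ANOVA
    with Dunnett's many-to-one post hoc comparisons, Student's t test, and
    four-parameter logistic dose-response fitting). A synthetic-data module
    simulates somatic CAG-repeat expansion in a cell population, PCR stutter,
    and rendered electropherograms with known ground truth, so every pipeline
    stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    optparse,
    jsonlite
Config/testthat/edition: 3
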