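Package: wormAgeQTL
Title: Age-Aware Expression QTL Mapping in Recombinant Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Linkage analysis of transcript abundance in two-parent
    recombinant inbred line (RIL) panels sampled at several ages, with
    chronological age rescaled to physiological age (age divided by the
    strain's mean lifespan). Provides single-marker and two-age
    marker-by-age linear models for eQTL detection, permutation-based
    genome-wide and joint false discovery rates, broad-sense heritability
    of expression (per age and over time), transgressive segregation
    statistics, forward/backward BIC model selection over multi-locus and
    epistatic terms, and hypergeometric gene-set over-representation.
    Includes a synthetic-data generator that emulates an N2 x CB4856
    C. elegans RIL study (Haldane map with selfed-RIL expansion) so every
    stage of the pipeline can be exercised and calibrated without
    microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
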