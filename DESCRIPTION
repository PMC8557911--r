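Package: sewerseq
Title: Sequence-Based Assessment of Human Sewage Pollution in Rivers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing human sewage pollution in river systems from
    16S rRNA amplicon sequence variant (ASV) communities and a human
    Bacteroides (HB) qPCR marker. Partitions ASVs into freshwater, human
    fecal, sewer, and uncategorized source categories by exact sequence
    matching against labelled reference databases with a percentile-based
    inclusion filter; quantifies the HB marker in copy number per 100 ml with
    censoring at the limits of detection and quantification and classifies
    samples into contamination categories; derives a risk threshold on the
    sewage-sequence relative abundance from a Monte Carlo mass-balance model
    with log-normal inputs (with an analytic small-fraction oracle); tabulates
    dual-threshold concordance; computes indicator-value specificity and
    sensitivity for ASVs against contamination categories; and provides
    Shannon and Simpson diversity, Bray-Curtis dissimilarity, and a one-factor
    permutational multivariate analysis of variance. A synthetic-data module
    generates reference databases, river ASV tables, and coupled qPCR
    observations with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
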