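Package: georecur
Title: Geostatistical Fuzzy Recurrence Analysis of CT Image Stacks
Version: 0.1.0
Authors@R: person("georecur", "developers", email = "georecur@example.org",
    role = c("aut", "cre"))
Description: Per-slice semi-variogram series from stacked-TIFF CT volumes,
    fuzzy recurrence plots built from time-delay embeddings via fuzzy c-means
    and max-min fuzzy-relation composition, fuzzy recurrence quantification
    (recurrence rate, determinism, laminarity, trapping time, divergence,
    entropy), alpha-cut fuzzy recurrence networks with graph properties, and a
    largest-recurrence-eigenvalue statistic obtained by iterated sharpening
    convolution, rectification and max pooling. Includes a synthetic CT-like
    volume and cohort generator so the whole pipeline is testable without
    external data, plus cohort summarization by group.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
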