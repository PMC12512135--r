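Package: tred
Title: Transcriptome-Informed Reversal Distance for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signature-reversion drug repositioning with the reversal-distance
    (TReD) framework. Disease signatures (TWAS Z-scores or differential-expression
    log fold changes) and LINCS-style drug response profiles are embedded as
    centered rank-ratio vectors in a shared gene space; each drug is scored by
    its reversal distance (the negated projection of the disease signature onto
    the drug profile direction), assessed by label-shuffle and degree-preserving
    network permutation tests, and prioritized by multi-signature consistency
    rules. A Kolmogorov-Smirnov connectivity-score baseline, GCT 1.3 and
    tabular readers/writers, and a synthetic-data generator with planted
    reverser drugs are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
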