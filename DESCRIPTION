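Package: peakcoloc
Title: Co-Localization Statistics for ChIP-seq Peak Sets
Version: 0.1.0
Author: peakcoloc developers
Maintainer: peakcoloc developers <peakcoloc@example.org>
Description: Statistical analysis of co-location between two genomic
    interval (peak) sets: overlap decomposition into common sections and
    Venn-style counts, domain-restricted per-region proximity p-values
    summarized as an Overlap Correlation Value (OCV), Monte Carlo and
    analytic spatial-correlation tests (interval-count permutation,
    relative-distance Kolmogorov-Smirnov, absolute-distance permutation,
    Jaccard permutation, projection binomial), TSS-window regulatory
    domain construction with region-to-gene association, and a synthetic
    cistrome generator with controllable co-location structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
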