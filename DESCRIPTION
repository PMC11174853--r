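Package: countshift
Title: Negative Binomial Count Modeling and Cumulative-Shift Statistics
    for Diurnal RNA-Seq Comparisons
Version: 0.1.0
Authors@R:
    person("countshift", "maintainers", email = "countshift@example.org",
           role = c("aut", "cre"))
Description: Implements a count-based pipeline for comparing the diurnal
    transcriptome of two genotypes measured at a small number of photoperiod
    time points with few replicates: greatest-depth transcript quantification
    from alignment intervals, housekeeping-gene normalization with a
    median-of-ratios size-factor check, NB2 dispersion-trend estimation by
    abundance binning with a gamma log-linear theta regression,
    outlier-trimmed per-gene mean estimation, Wald NB-GLM differential
    expression with Benjamini-Hochberg correction, an ECDF cumulative-shift
    permutation statistic for transcriptome and gene-set activity,
    simulated-count pair correlation, time-point-associated expression
    clustering, and Fisher over-representation with paralog adjustment.
    A fully specified synthetic-data generator emulates the assumed study
    design (2 genotypes x 4 time points x 3 replicates) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
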