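Package: triadbuffer
Title: Gene-Dosage Response and Homoeolog Buffering Analysis for Allopolyploid RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of the transcriptomic consequences of aneuploidy in
    allohexaploid wheat from bulk RNA-seq counts: per-gene log2(aneuploid/euploid)
    expression ratio profiles along chromosomes with tri-cube local polynomial
    (loess) smoothing, per-gene Pearson tests of transcript abundance against
    chromosome copy number with Benjamini-Hochberg FDR control, a transparent
    negative-binomial Wald test for differential transcription (median-of-ratios
    normalization, method-of-moments dispersions shrunk toward a mean-dispersion
    trend), and homoeolog triad analysis (summed A/B/D expression, one-way ANOVA
    for differentially transcribed triads, and seven-category ternary bias
    classification by nearest centroid). A karyotype-aware negative-binomial
    count simulator generates allohexaploid datasets with known dosage effects,
    triad structure and replicate noise so that every stage can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
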