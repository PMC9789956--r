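Package: gametrd
Title: Bayesian Transmission Ratio Distortion Scans with Gametic
    Interaction in Genotyped Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transmission ratio distortion (TRD) in sire-dam-offspring
    trio genotype data using a per-mating offspring probability model with
    direct transmission effects (alpha) and gametic interaction effects (beta)
    between the alleles inherited from each parent. Parameters are estimated
    per genomic region by componentwise Metropolis-Hastings sampling under
    flat priors, significance is assessed with Savage-Dickey density-ratio
    Bayes factors, and regions are screened with a strong-interaction
    magnitude filter. Includes a synthetic trio-data generator emulating
    cattle-breeding pedigree structure (few heavily reused sires), a scan
    driver over candidate regions, Mendelian-consistency screening, positional
    gene extraction around regions from GFF3 annotation, and hypergeometric
    over-representation analysis of the resulting gene lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
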