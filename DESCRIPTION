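Package: biasgl
Title: Mapping-Bias-Corrected Genotype Likelihoods for Low-Coverage Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies locus- and individual-specific mapping bias in short-read
    sequencing data by allele-flipped read remapping, and recalibrates genotype
    likelihoods at pre-ascertained biallelic SNPs accordingly. Includes the
    downstream estimators the correction is evaluated with (pseudohaploid calls,
    maximum-likelihood allele frequencies from genotype likelihoods, per-site f2
    differentiation, supervised admixture-proportion EM) and a synthetic-data
    generator with a parametric reference-bias read-loss process, so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
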