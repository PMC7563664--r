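Package: trdscan
Title: Genome Scans for Maternal Transmission Ratio Distortion from
    Dam-Offspring Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects maternal transmission ratio distortion (TRD) from
    SNP genotypes of dams and their offspring when sires are ungenotyped
    but known to come from one of two source populations. Each SNP is
    modelled with a multinomial likelihood in which a heterozygous dam
    transmits the major allele with probability 0.5 + alpha and the sire
    contributes an allele drawn at his population's frequency; the
    distortion parameter alpha and the two sire allele frequencies are
    estimated by constrained maximum likelihood and tested with a
    likelihood ratio test, with false discovery rate control across the
    genome. Includes the SNP quality-control cascade (call rate, family
    consistency, minor allele frequency, dam heterozygosity), readers for
    PLINK text and VCF genotypes, a command-line scan driver, and a
    family-genotype simulator for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    optparse,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
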