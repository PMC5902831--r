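Package: layerscan
Title: Recessive Lethal Haplotype Scans and Deleterious Variant Surveys
    in Layer Chicken Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of recessive lethal haplotypes from pedigreed,
    phased SNP-chip genotypes via missing homozygosity (sliding-window
    haplotype enumeration, parental-haplotype expected-homozygote counts,
    one-sided exact binomial deficit tests), together with sequence-level
    surveys of deleterious variation: variant catalogue QC and functional
    classification, allele-frequency spectra by functional class, pooled
    heterozygosity (zHp) selective-sweep scans, fixed and line-specific
    evolutionary-intolerant variant sets, recombination-rate versus
    purging-efficiency correlation, protein-position and indel-length
    signatures, and embryonic-lethal candidate filtering with hatchability
    comparison. Includes a pedigree gene-dropping simulator that generates
    phased populations with an embedded recessive lethal, an annotated
    variant catalogue, a genetic map, and hatchability records, so every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
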