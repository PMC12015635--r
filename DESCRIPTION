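Package: capsforge
Title: Design of CAPS/PCR-RFLP Markers from Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for developing cleaved amplified polymorphic sequence
    (CAPS, also called PCR-RFLP) markers from a reference genome and a
    multi-sample VCF. Candidate SNPs are filtered by biallelic status, minor
    allele frequency, missingness, and tiered exact Hardy-Weinberg tests with
    separate heterozygote-excess and heterozygote-deficit tails (the excess
    tail screens out pseudo-SNPs caused by co-mapping reads from duplicated
    regions). Surviving candidates are screened against duplicated genomic
    segments by local-alignment identity, pruned to an unlinked set by
    genotype-dosage r-squared, matched to restriction enzymes whose
    recognition site is created or destroyed by the SNP alleles, and turned
    into complete assay specifications with constraint-based primers placed
    in conserved flank regions, predicted amplicon and digest fragment
    sizes, and in-silico digest genotyping. A synthetic-data module
    generates genomes and partial-selfing populations with planted markers
    so the whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
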