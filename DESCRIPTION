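Package: gcaldb
Title: Combining-Ability Association Mapping with Multi-Allelic LD-Block Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the general combining ability (GCA) of
    hybrid-rice parents with genome-wide marker data. Estimates per-parent
    GCA effects for replicated North Carolina design II (NCII) crossing
    schemes with ANOVA and LSD letter grouping, partitions parental SNP
    genotypes into linkage-disequilibrium blocks by the confidence-interval
    (Gabriel) method, collapses each block into a multi-allelic haplotype
    marker (SNPLDB) with MAF, gene-diversity and PIC statistics, associates
    GCA effects with marker alleles by single-factor ANOVA, identifies
    superior alleles per trait polarity, tallies them across parents, and
    ranks cross combinations for allele pyramiding. Includes a synthetic-data
    generator for inbred parental panels and NCII phenotypes, plus a
    five-level grain-quality scoring utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
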