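Package: ystrkit
Title: Forensic and Population-Genetic Analysis of Y-STR Haplotypes
Version: 0.1.0
Authors@R:
    person("ystrkit", "developers", email = "ystrkit@example.org",
           role = c("aut", "cre"))
Description: Tools for forensic Y-chromosomal short tandem repeat (Y-STR)
    haplotype data: a data model for integer, intermediate, null and
    duplicated allele calls; nested marker-panel algebra for the common
    forensic kits (minimal haplotype, PowerPlex Y12, Yfiler 17,
    PowerPlex Y23, 26-locus systems); allele-frequency and haplotype-level
    forensic parameters (gene diversity, haplotype diversity, match
    probability, discrimination capacity); pairwise R_ST via analysis of
    molecular variance on squared repeat-size differences with permutation
    tests; classical multidimensional scaling and neighbor-joining trees of
    population distance matrices; multi-class linear discriminant analysis
    of allele sizes; and a stepwise-mutation forward simulator with
    admixture and typing-anomaly injection for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
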