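Package: hhscan
Title: Homozygosity Haplotype Mapping and Rare-Variant Prioritization in
    Multiplex Families
Version: 0.1.0
Authors@R:
    person("hhscan", "maintainers", email = "hhscan@example.org",
           role = c("aut", "cre"))
Description: Two-stage analysis of multiplex-family genotype data for
    disease-gene localization in founder populations. Stage one reduces
    each individual's SNP genotypes to a homozygosity haplotype
    (homozygous calls only), detects Regions with Conserved Homozygosity
    Haplotype (RCHH) bounded by discordant homozygous SNPs, selects
    representative regions shared by the largest set of affected family
    members, and compares patient versus control sharing with a pooled
    two-proportion z statistic; a seeded Monte Carlo check estimates the
    probability that genotyping error alone would break a region. Stage
    two filters annotated exome variants inside significant regions by
    functional class and population minor-allele frequency, counts
    affected and unaffected carriers, and summarizes gene overlap
    between families. A gene-dropping pedigree simulator with Haldane
    recombination and an implanted ancestral segment provides fully
    synthetic cohorts for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
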