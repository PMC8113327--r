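Package: ipnimmune
Title: Immunogenomic Analysis of the Preneoplasia to Invasive Lung
    Adenocarcinoma Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how the anti-tumour immune contexture evolves
    across ordered histologic stages of early lung adenocarcinoma (normal
    lung, atypical adenomatous hyperplasia, adenocarcinoma in situ, minimally
    invasive and invasive adenocarcinoma). Implements immune-panel count
    normalization (negative-control background correction, two-step
    geometric-mean scaling, quantile normalization, log2), one-way ANOVA
    differential expression with a beta-uniform mixture model to derive an
    FDR-controlled p-value cutoff, Fisher gene-set enrichment, TCR-beta
    repertoire metrics (clonality, inverse Simpson diversity, density,
    top-clone rank bins), allele-specific HLA loss-of-heterozygosity calling
    from binned logR/BAF with purity and ploidy adjustment, mutant 9-12-mer
    neoantigen enumeration with binding and promoter-methylation filters,
    multiplex-immunofluorescence phenotype gating, stage-trend and pairwise
    association statistics, and a seeded synthetic multi-stage cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
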