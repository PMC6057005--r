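Package: sgeGWAS
Title: GWAS for Direct and Indirect Genetic Effects on Survival in Group-Housed Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-model genome-wide association analysis of survival time in
    group-housed animals where an individual's phenotype depends both on its
    own genotype (direct genetic effects) and on the genotypes of its group
    mates (indirect or social genetic effects). Provides simulation of
    half-sib cage designs with known genetic architecture, PLINK-text
    genotype input and quality control with parental-mean imputation,
    pedigree relationship matrices, REML variance-component estimation for a
    linear survival-time model, a random-regression model for repeated
    binomial survival records and a logit generalized linear mixed model,
    simultaneous direct plus indirect SNP scans by generalized least squares
    with genomic control, Storey q-value false discovery rate control,
    backwards elimination with variance-explained accounting, and closed-form
    power calculations for direct versus indirect SNP effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
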