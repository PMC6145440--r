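Package: fgmhybrid
Title: Hybrid Fitness Landscapes Under Fisher's Geometric Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting and estimating the fitness of hybrids
    between diverged populations. Implements the closed-form expected
    breakdown landscape over hybrid index and interpopulation
    heterozygosity under Fisher's geometric model, forward simulation of
    parental divergence and hybrid genotypes in an n-trait phenotype
    space, an equivalent model of multilocus Dobzhansky-Muller
    incompatibilities, extensions to sex chromosomes (Haldane's rule,
    hemizygosity, paternal X silencing), estimation of ancestry
    coordinates from diagnostic marker tables, and GLM-based estimation
    of the hybrid fitness surface with AIC model selection and profile
    confidence intervals. A seeded synthetic-data generator produces
    marker datasets with the Mendelian structure of F1/F2/backcross and
    wild-hybrid designs so the whole pipeline can be validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
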