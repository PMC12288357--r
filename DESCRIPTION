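Package: twinmeth
Title: Bivariate Twin Models for Genetic Influence on DNA Methylation-Obesity Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how much of an observed association between
    DNA methylation and an anthropometric trait is driven by shared genetics,
    using paired twin data. Fits bivariate ACE/ADE Cholesky structural
    equation models per CpG site with AIC model selection and one-sided
    likelihood-ratio constraint tests, derives phenotypic, genetic and
    unique-environmental correlations (Rph, Ra, Re), estimates CpG-trait
    associations with linear mixed models in the full population and in the
    monozygotic within-pair difference design, stratifies CpGs into
    evidence-based groups (including meQTL/GWAS SNP overlap), and classifies
    each association into one of four genetic-influence outcomes. Includes a
    twin-cohort simulator with known path coefficients for calibration and
    power studies, plain-text cohort I/O, SNP-panel zygosity calling, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    parallel,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
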