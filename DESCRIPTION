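Package: prsforge
Title: Development and Validation of Polygenic Risk Scores for Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to develop and validate small-panel polygenic risk scores
    (PRSs) for case-control studies, modelled on the two-cohort design used
    in breast-cancer genetic epidemiology: a GWAS-scale training cohort and
    an external case-control validation cohort. Provides a synthetic cohort
    generator (Hardy-Weinberg genotypes with block linkage disequilibrium,
    additive-logistic disease liability with covariate and SNP-SNP
    interaction effects, estrogen-receptor subtypes, sporadic missingness,
    duplicate and related samples), deterministic genotype quality control
    (exact Hardy-Weinberg test, KING-robust kinship, duplicate concordance,
    call-rate/MAF filters, population-mean imputation), SNP selection
    (composite-LD r2, proxy substitution, greedy LD pruning, significance
    and effect-direction filters), three PRS weighting approaches (per-SNP
    repeated logistic regression; multivariate logistic ridge regression
    with covariate adjustment and 10-fold cross-validated penalty; an
    artificial neural network with a linear bottleneck trained by Adam), and
    an evaluation suite (odds ratio per control interquartile range, extreme
    quartile odds ratio, AUC with Hanley-McNeil confidence intervals, decile
    observed/expected odds-ratio calibration, covariate residual adjustment,
    and a pairwise SNP-SNP interaction scan with Bonferroni correction).
    Includes PLINK text-format (.ped/.map, .raw) and TSV readers/writers and
    an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
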