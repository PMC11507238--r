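Package: pigmentr
Title: Forensic DNA Phenotyping of Eye, Hair and Skin Colour from SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for evaluating forensic DNA phenotyping of human
    pigmentation from small SNP panels in the HIrisPlex-S tradition.
    Provides multinomial logistic regression prediction of eye, hair and
    skin colour from effect-allele dosages, probability-threshold calling
    with strict and flexible interpretation rules, concordance scoring
    against observed phenotypes with the full contingency-table metric
    suite (accuracy, AUC, sensitivity, specificity, PPV, NPV), forward
    AIC model selection with repeated stratified k-fold cross-validation,
    Hardy-Weinberg and allele-frequency quality control, and a calibrated
    synthetic genotype-phenotype cohort generator so the whole pipeline
    can be exercised without access to restricted study data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    nnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
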