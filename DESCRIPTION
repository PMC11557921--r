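Package: lodsebi
Title: Organ Dysfunction and Early Brain Injury Scoring After Aneurysmal
    Subarachnoid Hemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Logistic Organ Dysfunction System (LODS) score
    from first-24-hour physiology (with and without the Glasgow Coma Scale
    component), a composite early-brain-injury (EBI) grade built from
    persistent loss of consciousness, global cerebral edema and total
    intracranial blood burden (Hijdra cisternal score, Le Roux
    intraventricular score and ABC/2 hematoma volumetry), and the Charlson
    comorbidity index.  Provides the downstream discrimination analysis
    (ROC/AUC with Hanley-McNeil confidence intervals, Youden cutoff
    selection, two-by-two diagnostic metrics, odds ratios, logistic and
    multivariate linear regression, order-statistic median confidence
    intervals) and a seeded latent-trait synthetic cohort generator for
    end-to-end testing without patient-level data.
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
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
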