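Package: csascreenr
Title: Rule-Based Detection of Childhood Sexual Abuse in Clinical Notes and
    Analysis of Its Clinical Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies recorded histories of childhood sexual abuse (CSA) in
    free-text electronic health records of patients with severe mental illness
    using a string-matching lexicon with exclusion rules and age-slot
    templates, and quantifies demographic, clinical and functional correlates
    and clinical outcomes (psychiatric admissions, antipsychotic dosing).
    Includes a seeded synthetic-cohort generator emulating a ~7000-patient
    severe-mental-illness registry with notes, HoNOS assessments, admissions
    and medication mentions; a simplified gazetteer-based antipsychotic dose
    extractor reporting percentages of the maximum recommended daily dose;
    cohort filters and outcome derivations; and an epidemiological layer with
    Pearson chi-square tests, 2x2 odds ratios with Woolf confidence intervals
    and covariate-adjusted logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
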