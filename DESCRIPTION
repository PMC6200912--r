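Package: rsnvar
Title: Test-Retest Variability of Resting-State Networks on Parcellated
    Connectomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying within-session test-retest variability of
    resting-state fMRI networks on parcellated (region-level) data, aimed at
    single-subject studies such as disorders-of-consciousness assessments.
    Provides spatial independent component analysis with an 11-dimensional
    component "fingerprint" for neuronal versus artifactual classification,
    template goodness-of-fit network assignment across nine canonical
    resting-state networks, edge-weight graphs with a 0-to-1 threshold sweep
    and node graph strength, the ratio-of-fit (ROF) statistic with its
    test-retest difference (delta ROF), best-acquisition selection, regional
    PET-uptake to graph-strength coupling, rigid-body motion summaries, and a
    fully seeded synthetic-data generator so that every stage is testable
    without clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
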