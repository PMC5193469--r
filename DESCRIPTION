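Package: FISHcall
Title: Automated Chromosome-Arm Status Calling from Interphase FISH Spot Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies interphase nuclei from dual-colour FISH red/green
    spot counts, calls tumour-level chromosome-arm status (deleted,
    imbalanced, normal) for 1p, 9p, 10q and 19q using calibrated
    percentage-of-nuclei cutoffs, and derives integrated WHO-2016 diagnoses
    for diffuse gliomas from the combination of histology,
    immunohistochemistry and molecular status. Includes a clonal-mixture
    simulator of spot counts under a lossy detection model (per-spot
    dropout from nuclear truncation, background spots, signal splitting),
    mean + 3 SD cutoff calibration on non-neoplastic controls, Cohen's
    kappa concordance between manual and automated scoring, and the
    cohort-level statistical toolkit (chi-square group comparisons,
    deleted-arm counts, Kaplan-Meier, log-rank and Cox survival analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, survival, yaml
Suggests: testthat (>= 3.0.0), e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
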