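Package: cardiomiR
Title: miRNA Seed-Site Targetome Screening and Cardiac Electrophysiology Trace Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for identifying microRNAs that regulate the
    cardiac action potential. Scans 3' UTR sequences for canonical miRNA seed
    sites (8mer, 7mer-m8, 7mer-A1), builds binding-site count matrices over a
    panel of repolarizing ion-channel genes and ranks miRNA seed families by
    site burden; tests predicted targetomes for disease-term enrichment
    (hypergeometric/Fisher) and for coherent fold-change shifts in
    differential-expression tables; quantifies double-fluorescent reporter
    repression from per-cell intensity tables; extracts APD90 with Bazett rate
    correction from optical action-potential traces, corrects field-potential
    durations, and assembles patch-clamp IV curves with leak and drug
    subtraction; and determines the effective refractory period of paced
    myocardial tissue from S1-S2 twitch-force recordings. Every input can be
    produced by the built-in synthetic-data generators with known ground
    truth, so the whole pipeline runs and is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
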