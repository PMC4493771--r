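Package: dtakit
Title: Digital Transcript Abundance Profiling of Ethylene-Induced Fruit
    Abscission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for unreplicated tag-based digital
    transcript abundance (DTA) expression profiling, built around the
    seven-library time-course design used to study ethephon-induced
    fruitlet abscission in litchi (control libraries CK0-CK3 and treated
    libraries ETH1-ETH3). Provides RPKM normalisation and library
    bookkeeping, the Audic-Claverie exact test for differential
    expression between two unreplicated count libraries with
    Benjamini-Hochberg FDR and a fold-change gate, control-background
    subtraction and the union into a treatment-responsive gene set,
    hypergeometric GO/KEGG term enrichment with candidate-gene
    screening, classification of candidates into four temporal response
    groups with sub-clustering, delta-delta-Ct qPCR relative
    quantification with concordance scoring against the DTA profiles,
    and a negative-binomial synthetic data generator with planted truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
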