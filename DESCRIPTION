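Package: vitimet
Title: Rule-Based MS2 Annotation and Quantitative Profiling for Grape Berry Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annotation and profiling pipeline for untargeted LC-MS/MS
    metabolomics of grape berries. Annotates positive-mode MS2 spectra of
    glycosylated and acylated flavonoids by neutral-loss ladder decomposition
    against a registry of aglycones and modifications, and classifies
    oleanane-type pentacyclic triterpenoids by diagnostic fragment ions.
    Downstream profiling covers internal-standard and Z-score normalization,
    absolute quantitation from calibration series, differential-accumulation
    screening by Student's t-test, nested analysis of variance (variety within
    berry color), presence-intersection counts across color classes, principal
    component analysis, and hierarchical clustering. A seeded synthetic-data
    generator produces ground-truthed compound libraries, MS2 spectra and
    color-structured abundance matrices so that every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
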