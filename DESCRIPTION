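Package: metaboMatch
Title: Metabolite Annotation of Tandem Mass Spectra Against Indexed
    Compound Stores
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates peak-picked tandem mass spectra of small molecules
    by retrieving candidate compounds from an indexed HDF5 compound store,
    filtering them by mass window, molecular formula, elemental composition
    and metabolite likeness, and ranking them with two complementary
    scorers: an in-silico bond-cleavage fragmentation matcher and a
    per-bit SVM molecular-fingerprint predictor ranked by Jaccard
    similarity. Scores from enabled scorers are fused multiplicatively
    into a total score, and ranked annotations are written as hierarchical
    text and HTML reports. Includes a synthetic fixture generator (toy
    compound sets and simulated spectra with known ground truth) so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    ChemmineR,
    ChemmineOB,
    rhdf5,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
biocViews: MassSpectrometry, Metabolomics, Cheminformatics, Annotation
RoxygenNote: 7.3.3
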