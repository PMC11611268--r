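Package: funtaxa
Title: Functional Profiling and Robust Feature Selection for Microbiome
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates taxonomic microbiome abundance tables into
    functional-annotation score profiles (abundance-weighted counts of GO
    terms and EC numbers carried by each taxon's proteome), optionally
    weighted by the TF-IGM scheme, and classifies disease versus control
    samples with seeded ensembles of grid-searched random forests.
    Iterative importance-based variable selection with an automated elbow
    cutoff, repeated over independent runs, yields consensus shortlists of
    Robust, Confident and Candidate discriminant taxa and annotations,
    together with taxon-annotation linkage analytics (link strengths,
    profile assignment, functional-redundancy screens and annotation
    categories). A synthetic-data generator with planted group effects
    makes the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
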