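Package: timegeo
Title: Mining Time-Point Structure and Disease Annotations from
    Gene-Expression Series Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based extraction of time-course structure from the
    unstructured metadata of gene-expression series (GEO SOFT files or
    GEOmetadb-style tables). Determines the number of distinct time
    points in an experiment from explicit statements, listings of time
    values, approximate temporal phrases, and number+unit tokens in
    sample titles, validated by arithmetic/geometric-progression checks
    and confounder rules. Also annotates series with Disease Ontology
    terms via a dictionary matcher over names and synonyms, generates
    synthetic metadata corpora with known ground truth, and scores
    extraction accuracy (exact and within-one-time-point), stratified by
    true time-point count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
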