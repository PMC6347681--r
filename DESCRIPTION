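Package: repevol
Title: Population Genetics of Somatic Evolution in Antibody Repertoires
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying somatic evolution of clonal B-cell lineages
    from immune repertoire sequencing. Identifies clonal lineages by
    germline-gene grouping and single-linkage CDR3 clustering, classifies
    lineage dynamics around a vaccination time course, builds site frequency
    spectra of somatic mutations against personalized germline references,
    scores selection with Fay and Wu's H against Kingman, expanding-population
    and Bolthausen-Sznitman coalescent null models, detects positively
    selected subclones on lineage phylogenies by greedy breadth-first search,
    and ranks sequences and mutations by phylogenetically inferred fitness
    (local branching index) with regional dN/dS summaries. Includes a
    synthetic repertoire generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
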