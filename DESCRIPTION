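Package: genovmap
Title: Dating and Classifying Gene-Family Origins on a Species Phylogeny
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assigns each orthogroup's node of origin on a rooted species
    tree by MRCA parsimony, classifies novel gene families by likely mode
    of origin (duplication and divergence, horizontal gene transfer, or
    de novo candidate) from taxon-partitioned homology evidence and
    protein-domain annotation, screens families for retention and for
    significant copy-number expansion with an Anderson-Darling,
    Kruskal-Wallis and Dunn post-hoc cascade, and tests local gene-order
    (microsynteny) conservation with flanking marker genes.  Includes a
    gene birth-loss-duplication simulator on trees so every stage of the
    analysis can be exercised end-to-end with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    data.table,
    igraph,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
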