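Package: tandemdup
Title: Tandem Gene Duplication Detection and Duplicate-Class Analysis for
    Genome Annotations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects tandem duplicated gene clusters in an annotated genome
    from gene order and paralogous-group membership, using three criteria:
    shared paralogous/orthologous group, a bounded number of intervening
    genes on the same scaffold, and a bounded pairwise gene distance.
    Companion analyses cover chi-squared over/under-representation of GO
    categories in duplicate gene classes, assembly summary metrics (scaffold
    and contig N50, N-gap accounting, length filtering), identity/coverage
    best-hit identification of candidate pathway orthologs, scanning
    scaffolds for physical neighborhoods of pathway homologs, and
    multi-species orthogroup partition counts. A synthetic-annotation
    generator with planted tandem arrays, dispersed duplicates, similarity
    tables and GO maps provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
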