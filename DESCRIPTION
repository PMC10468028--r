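Package: annorefine
Title: Evidence-Based Refinement of Draft Genome Annotations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of draft genome annotations for large repeat-rich
    plant genomes. Takes ab initio gene predictions and transcriptome-alignment
    gene models (GFF3) together with a softmasked genome (FASTA), protein-domain
    tables and similarity-search hit tables, and produces a filtered, merged,
    provenance-tracked gene set. Implements structural validation of coding
    models (minimum CDS, exon and intron sizes, start and stop codons, in-frame
    stop scanning), removal of repeat-dominated and transposable-element models,
    reciprocal query/target coverage filtering, nested and partially overlapping
    model resolution against transcript evidence, summary statistics, and a
    deterministic synthetic-fixture generator with planted defects for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    seqinr,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
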