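Package: orthrefine
Title: Orthology-Guided Refinement of Protein Annotations from De Novo
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines de novo transcriptome assembly contigs for the coding
    sequence of a gene whose annotation may be incomplete, using a
    well-annotated orthologous protein ("bait") from a related species.
    Provides six-frame translated local homology search with
    Karlin-Altschul bitscore and E-value statistics, reciprocal best-hit
    validation against a reference proteome, open reading frame
    prediction and longest-ORF protein reconstruction, quantification of
    the refinement by directional pairwise sequence identities and
    alignment coverage, a mean + 2 SD outlier rule for flagging
    presumably poorly annotated orthologues from orthology identity
    tables, assembly summary metrics, and a deterministic synthetic-data
    generator (ortholog families, contig fragmentation, truncated
    annotations) for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
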