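---
title: "Orthology-guided refinement of protein annotations from transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthology-guided refinement of protein annotations from transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthrefine)
```

## The problem

Protein annotations in non-model vertebrates are frequently incomplete:
an orthologue may be missing an N-terminal stretch because a start site
or splice site was mis-annotated, or may be too long because a stop was
missed. When a well-curated orthologous protein from a related species
exists (the *bait*), and RNA-Seq data from the target species is
available, the true coding sequence is usually sitting in a de novo
transcriptome assembly — it only has to be found, translated and
compared. `orthrefine` implements that workflow at desk scale:

1. **Forward search** — the bait protein is aligned to every assembly
   contig in all six reading frames (a tblastn-style translated search),
   hits are ranked by bitscore and E-value, and the *n* best contigs are
   selected.
2. **ORF selection** — the best contig's open reading frames are
   enumerated and its longest ORF becomes the candidate (refined)
   protein.
3. **Validation** — a reverse (blastx-style) search of the contig
   against the full reference proteome establishes whether bait and
   contig are reciprocal best hits (RBH), the standard operational
   criterion for orthology; and a small multiple sequence alignment is
   emitted for visual inspection.
4. **Quantification** — the refinement is measured by directional
   pairwise identities against the bait before and after replacing the
   annotated target sequence.
5. **Flagging** — independent of any assembly, per-species tables of
   orthology identities are screened for genes whose annotation is
   likely poor, using a mean + 2 SD outlier rule.

## The search model

The aligner is a full Smith–Waterman with affine gaps (BLOSUM62, gap
open 11, gap extension 1; a length-*k* gap costs `11 + k`). We
deliberately use exact alignment rather than a seeded heuristic: the
package targets single-gene refinement and simulation studies, not
proteome-scale scans, and correctness of the ranking is the contract. A
plug-in path (`read_outfmt6()`) accepts externally computed tabular
alignments for large runs.

Raw scores are normalised to bitscores with the Karlin–Altschul
parameters published for gapped BLOSUM62/11/1, \(\lambda = 0.267\) and
\(K = 0.041\):

\[ S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad
   E = m \, n \, 2^{-S'} \]

with \(m\) the query length and \(n\) the total residue count of the
six-frame-translated database. No edge-effect length correction is
applied; reproducing a specific BLAST+ E-value to the digit is a
non-goal, but ordering fidelity and the significance cutoff
(default `1e-4`) are honoured. One HSP is kept per (contig, strand,
frame) — the single best; HSP chaining and sum statistics are not
implemented because the pipeline consumes only best-hit ordering. Stop
codons in translated frames are not alignment barriers; `*` simply
scores through its BLOSUM62 column (−4 against residues, +1 against
itself), which suppresses alignments across frame-breaking stops
without splitting frames.

Ties after (bitscore, E-value) are broken lexicographically on subject
id, so results are deterministic.

## ORF model

`find_orfs()` scans all six frames. A stop-delimited segment yields a
*complete* ORF from its first ATG to the stop; a frame whose first
segment contains no ATG before the first stop yields a flagged
*5'-partial* ORF (frame start to stop); an ATG with no downstream stop
yields a *3'-partial* ORF (ATG to frame end). Partials are reported —
and by default eligible as the "longest ORF" — because assembly contigs
need not span whole transcripts; excluding them would make refinement of
truncated contigs impossible. Nested internal ATGs are not reported
separately, and no coding-potential model is applied: selection is
purely by translated length, with ties broken complete-before-partial,
plus-strand-before-minus, then smaller forward-strand start. The
default `min_aa = 100` mirrors the common long-ORF convention and is
configurable down to 1.

## Identity and coverage arithmetic

Two conventions coexist deliberately:

* **Directional identities** (`pairwise_identity()`): matches are
  counted over a *global* (end-to-end, affine, end gaps penalised)
  alignment and divided by each sequence's full ungapped length — the
  orthology-database convention. If 98% of the orthologue matches the
  reference (*target identity*) but only 80% of the reference matches
  the orthologue (*query identity*), the difference of 18 points
  signals a missing fragment. The per-alignment-column identity is also
  stored for tabular-format compatibility.
* **Coverage** (`query_coverage()`): the aligned span over the sequence
  length, `100 (qend − qstart + 1)/qlen`, computed from a *local*
  alignment. This is the fallback quantification when no annotated
  target exists.

`refinement_delta()` reports, in identity mode, the absolute difference
of the two directional identities for the old annotation and for the
refined sequence, and their decrease; both signed and absolute values
are kept, since the flagging rule uses the absolute difference while
inspection plots are usually signed.

## Flagging model

For each species, the signed difference (target − query identity) is
computed per gene; the threshold is the mean of the *absolute*
differences plus twice their sample (n−1) standard deviation, and genes
whose absolute difference exceeds it are flagged. Whether the location
and scale should be computed on signed or absolute differences is
genuinely ambiguous; absolute is the default here (it is the quantity
the rule thresholds), signed is exposed via `absolute = FALSE`. The
cross-species filter then keeps genes flagged in exactly one species
among genes with records in every species — a divergence visible in one
species but not its relatives points at annotation rather than
evolution. Genes missing records in some species are excluded from the
filter rather than treated as unflagged.

## The synthetic world

`sim_config()` / `simulate_family()` state a small but explicit world
whose defaults are fixed once:

* 50 genes of 300–600 aa (typical vertebrate protein sizes, and the
  regime used by the end-to-end recovery tests);
* one related species at 0.9 protein identity — the conserved-vertebrate
  regime; orthologues are derived by codon-level point substitutions
  (`round((1 − t) L)` positions changed to codons of different amino
  acids), so realised identity is exact up to rounding and translations
  never gain internal stops. No indel model is applied by default; the
  pipeline's identity arithmetic is exercised through truncation
  instead;
* contig sets made of an optional guaranteed full-length CDS copy plus
  normally distributed fragments (mean 400, sd 100, min 300 nt),
  each reverse-complemented with probability 0.5;
* binary expression (`p_expressed`): unexpressed genes emit no contigs —
  sufficient to reproduce the qualitative dependence of RBH detection on
  expression without modelling read counts;
* truncated annotations: 20% of genes lose 10–40% of their length at
  the N terminus, emulating the mis-annotated-start case that motivates
  the method.

Everything is deterministic under the configured seed (the fragmenter
uses a seed offset by one so it can be re-run standalone).

What the generator does **not** emulate: sequencing error, chimeric or
misassembled contigs, alternative isoforms, paralogy beyond simple
duplicated families, and real codon usage. A green recovery test
therefore establishes the correctness of the pipeline's logic and
arithmetic on clean input — not robustness to assembly artefacts.

## Numerical and design choices

* Internal coordinates are 0-based half-open; all serialised alignment
  coordinates are 1-based inclusive (the tabular-format convention),
  with `sstart > send` marking the minus strand.
* On ingest, `U` is mapped to `T` and other IUPAC ambiguity codes to `N`
  with a warning, because real assemblies contain them; characters
  outside the alphabet are errors naming record and position. Only
  translation table 1 is supported (vertebrate nuclear genes). Codons
  containing `N` translate to the unambiguous amino acid when all
  completions agree, otherwise `X`.
* The reverse (validation) search uses the whole best contig by default,
  with a longest-ORF mode available; the mode used is recorded in the
  result. Reciprocity is decided on the top-ranked contig only, and
  reverse hits are matched on exact sequence id.
* The MSA is a centre-star progressive alignment ("once a gap, always a
  gap"), adequate for visual inspection; export the unaligned FASTA to
  a dedicated aligner for publication-grade alignments.
* The mean + 2 SD threshold requires at least two values; detection
  rates require a positive bait count; degenerate inputs (contig < 3 nt,
  all-`N` contigs, empty search results) yield empty results, not
  errors, except where a contract is violated.

## Known limitations

Alignment is quadratic per pair, so whole-proteome runs should use the
external-alignment plug-in path. E-values are comparable within a run
but are not BLAST+ replicas. The flagging rule inherits the usual
weakness of mean + 2 SD screens: with few genes per species an outlier
inflates its own threshold (at five genes a lone difference of 30
points does not exceed the threshold it induces), so the rule is only
meaningful on genome-scale tables. One-to-one orthology is assumed
throughout; mapping between identifier namespaces is the caller's
concern.
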