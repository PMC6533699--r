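# orthrefine

Orthology-guided refinement of protein annotations from de novo
transcriptome assemblies.

## The problem

Protein annotations in non-model species are often incomplete — a
mis-annotated start or splice site leaves the recorded orthologue
missing (or carrying extra) sequence relative to its well-curated
counterpart in a related species. When RNA-Seq data from the target
species exists, the true coding sequence is usually present in a de
novo transcriptome assembly. `orthrefine` finds it: a well-annotated
orthologous protein (the *bait*) is aligned to the assembly contigs
over all six reading frames, the best contig's longest open reading
frame becomes the refined protein, and the refinement is quantified and
validated. The package is aimed at annotation curators and comparative
genomicists working gene-by-gene, and at method evaluation through its
fully deterministic simulator.

## Method at a glance

* **Translated search** (`search()`, `reverse_search()`): Smith-Waterman
  local alignment with affine gaps (BLOSUM62, open 11 / extend 1)
  against all six frame translations, scored with Karlin-Altschul
  statistics, bitscore S' = (λS − ln K)/ln 2 with λ = 0.267, K = 0.041,
  and E = m·n·2^(−S'); hits ranked by bitscore, E-value, subject id, and
  filtered at E ≤ 1e−4.
* **ORF prediction** (`find_orfs()`, `longest_orf()`): complete
  (ATG→stop) and flagged 5'-/3'-partial ORFs in all six frames; the
  longest translation represents the contig.
* **Reciprocal best hit** (`reciprocal_best_hit()`,
  `detection_rate()`): a bait is validated when the top contig's best
  reverse hit in the reference proteome is the bait itself.
* **Refinement quantification** (`pairwise_identity()`,
  `refinement_delta()`): directional identities from a global
  alignment — percent of each full sequence matching the other, the
  orthology-database convention; the refinement is the decrease in
  their absolute difference. Without an annotated target, alignment
  coverage of refined vs bait is compared instead.
* **Flagging** (`flag_genes()`): per species, genes whose absolute
  (target − query) identity difference exceeds mean + 2 SD are marked
  as presumably poorly annotated; a cross-species filter keeps
  single-species outliers only.
* **Simulation** (`sim_config()`, `simulate_family()`,
  `fragment_transcripts()`): ortholog families at controlled identity,
  fragmented randomly stranded contigs, truncated annotations — with
  full ground truth, for end-to-end validation.

## Worked example

Simulate ten genes whose annotations are partly truncated, then refine
them from their (full-length) contigs:

```r
library(orthrefine)

cfg <- list(n_genes = 10, len_range = c(200, 300),
            species_identity = list(bait = 1.0),
            n_fragments = 0, trunc_fraction = 0.3, seed = 7)
cmd_simulate(cfg, "fixture")

res <- cmd_refine(list(contig_fasta = "fixture/contigs.fasta",
                       bait_fasta = "fixture/baits_bait.fasta",
                       target_fasta = "fixture/annotated.fasta",
                       out_dir = "refined"))
subset(res$report, delta_identity > 0,
       c(bait_id, best_contig, old_abs_diff, refined_abs_diff,
         delta_identity))
```

```
  bait_id best_contig old_abs_diff refined_abs_diff delta_identity
2    g002     g002_c1     14.89362                0       14.89362
3    g003     g003_c1     29.13043                0       29.13043
5    g005     g005_c1     33.58491                0       33.58491
```

Three annotations were truncated in this world. For `g005`, the
annotated protein had lost 33.6% of its residues: only 66.4% of the
bait matched it, while 100% of it matched the bait, an absolute
identity difference of 33.6 points. After refinement the recovered
protein matches the bait end to end (difference 0), so the full
truncation is repaired — `delta_identity` equals the truncated
percentage. The output directory also contains the best contigs, the
ORF peptides, one MSA per bait for visual inspection
(`refined/msa_g005.fasta`), and a machine-readable log.

A shell entry point wrapping the same commands ships in
`inst/cli/orthrefine.R`:

```sh
Rscript inst/cli/orthrefine.R refine --config run.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the main computation from scratch on a
seeded synthetic fixture — simulation, refinement, reciprocal-best-hit
evaluation and assembly metrics — and writes its JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
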