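# Codon bookkeeping for the simulator (standard code, table 1).
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

#' Configuration for the synthetic ortholog-family generator
#'
#' The generator states a small but realistic world: a set of
#' single-isoform genes in a target species, orthologous bait proteomes
#' in related species at a controlled protein identity, a transcriptome
#' "assembly" made of (possibly fragmented, randomly stranded) substrings
#' of the expressed genes' coding sequences, and an annotated proteome in
#' which a fraction of genes is N- or C-terminally truncated (simulated
#' poor annotation).
#'
#' @param n_genes number of genes (default 50).
#' @param len_range protein length range in residues (default 300-600,
#'   typical vertebrate protein sizes).
#' @param species_identity named numeric in (0, 1]: per-species target
#'   protein identity of the bait orthologues (default one species at
#'   0.9, the conserved-vertebrate regime).
#' @param frag_mean,frag_sd,frag_min fragment length distribution in nt
#'   (normal, clamped below at `frag_min`).
#' @param n_fragments random fragments per expressed gene, in addition
#'   to the optional guaranteed full-length contig (default 2).
#' @param full_length_contig emit one full-length CDS contig per
#'   expressed gene (default TRUE).
#' @param p_expressed probability that a gene is expressed and thus
#'   yields contigs (default 1).
#' @param trunc_fraction fraction of genes whose annotation is truncated
#'   (default 0.2).
#' @param trunc_range truncation size as a fraction of protein length
#'   (default 0.1-0.4).
#' @param trunc_end `"N"` or `"C"` terminus (default `"N"`, the
#'   missing-N-terminus case motivating the method).
#' @param paralog_n number of genes that get a paralog (default 0).
#' @param paralog_identity protein identity of paralog to parent
#'   (default 0.7).
#' @param seed RNG seed (integer).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L, len_range = c(300L, 600L),
                       species_identity = c(speciesA = 0.9),
                       frag_mean = 400, frag_sd = 100, frag_min = 300,
                       n_fragments = 2L, full_length_contig = TRUE,
                       p_expressed = 1, trunc_fraction = 0.2,
                       trunc_range = c(0.1, 0.4), trunc_end = "N",
                       paralog_n = 0L, paralog_identity = 0.7,
                       seed = 1L) {
  stopifnot(n_genes >= 1, length(len_range) == 2,
            len_range[1] >= 10, len_range[2] >= len_range[1],
            p_expressed >= 0, p_expressed <= 1,
            trunc_fraction >= 0, trunc_fraction <= 1,
            all(trunc_range > 0), all(trunc_range < 1),
            trunc_end %in% c("N", "C"),
            paralog_n >= 0, paralog_n <= n_genes,
            paralog_identity > 0, paralog_identity <= 1)
  if (is.null(names(species_identity)) ||
      any(!nzchar(names(species_identity))))
    stop("species_identity must be a named vector")
  if (any(species_identity <= 0 | species_identity > 1))
    stop("species identity targets must be in (0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

# Replace k codons (never the start codon) by codons of a different
# amino acid, giving a realised protein identity of exactly (L - k)/L.
mutate_codons <- function(codons, k) {
  L <- length(codons) - 1L  # coding codons, excl. the stop
  if (k == 0) return(codons)
  stopifnot(k <= L - 1L)
  gc <- Biostrings::GENETIC_CODE
  sense <- sense_codons()
  pos <- sample(2:L, k)
  for (p in pos) {
    aa <- gc[[codons[p]]]
    alt <- sense[gc[sense] != aa]
    codons[p] <- sample(alt, 1)
  }
  codons
}

#' Simulate an ortholog gene family with ground truth
#'
#' Generates, per gene, an ancestral coding sequence (ATG, uniformly
#' random sense codons, a random stop), per-species bait orthologues by
#' codon-level point mutation to the configured identity (realised
#' identity is exact up to rounding: `round((1 - t) * L)` residues
#' changed), optional paralogs, and an annotated target proteome with
#' the configured truncations. Fully deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return A list of class `sim_family`: `cds` (nucleotide
#'   [seq_records], the target species' true coding sequences),
#'   `proteins` (true target proteins), `annotated` (annotated proteome,
#'   truncated where stated), `baits` (named list of per-species protein
#'   [seq_records]; ids equal gene ids), and `truth` (data frame:
#'   `gene_id`, `len_aa`, `truncated`, `trunc_k`, `trunc_end`,
#'   `paralog_of`).
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sense <- sense_codons()
  stops <- stop_codons()
  ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  lens <- sample(cfg$len_range[1]:cfg$len_range[2], cfg$n_genes,
                 replace = TRUE)
  genes <- list()
  for (i in seq_len(cfg$n_genes)) {
    codons <- c("ATG", sample(sense, lens[i] - 1L, replace = TRUE),
                sample(stops, 1))
    genes[[ids[i]]] <- codons
  }
  # paralogs of the first paralog_n genes
  paralog_of <- stats::setNames(rep(NA_character_, cfg$n_genes), ids)
  if (cfg$paralog_n > 0) {
    for (i in seq_len(cfg$paralog_n)) {
      pid <- paste0(ids[i], "p")
      k <- round((1 - cfg$paralog_identity) * lens[i])
      genes[[pid]] <- mutate_codons(genes[[ids[i]]], k)
      paralog_of[pid] <- ids[i]
    }
  }
  all_ids <- names(genes)
  all_lens <- vapply(genes, length, integer(1)) - 1L
  cds_seq <- vapply(genes, paste, character(1), collapse = "")
  proteins <- vapply(cds_seq, function(s) {
    p <- translate(s, 0L)
    substr(p, 1, nchar(p) - 1L)
  }, character(1))
  # per-species bait orthologues
  baits <- lapply(names(cfg$species_identity), function(sp) {
    t <- cfg$species_identity[[sp]]
    bs <- vapply(all_ids, function(g) {
      k <- round((1 - t) * all_lens[[g]])
      s <- paste(mutate_codons(genes[[g]], k), collapse = "")
      p <- translate(s, 0L)
      substr(p, 1, nchar(p) - 1L)
    }, character(1))
    seq_records(all_ids, bs, "protein",
                description = paste("ortholog", sp))
  })
  names(baits) <- names(cfg$species_identity)
  # truncated annotations (primary genes only, never paralogs)
  n_trunc <- round(cfg$trunc_fraction * cfg$n_genes)
  trunc_genes <- if (n_trunc > 0) sample(ids, n_trunc) else character(0)
  annotated <- proteins
  trunc_k <- stats::setNames(rep(0L, length(all_ids)), all_ids)
  for (g in trunc_genes) {
    frac <- stats::runif(1, cfg$trunc_range[1], cfg$trunc_range[2])
    k <- max(1L, min(all_lens[[g]] - 1L, round(frac * all_lens[[g]])))
    annotated[[g]] <- truncate_annotation(proteins[[g]], k,
                                          cfg$trunc_end)
    trunc_k[g] <- k
  }
  truth <- data.frame(
    gene_id = all_ids, len_aa = all_lens,
    truncated = all_ids %in% trunc_genes,
    trunc_k = as.integer(trunc_k),
    trunc_end = ifelse(all_ids %in% trunc_genes, cfg$trunc_end, NA),
    paralog_of = unname(paralog_of[all_ids]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    cfg = cfg,
    cds = seq_records(all_ids, unname(cds_seq), "nucleotide"),
    proteins = seq_records(all_ids, unname(proteins), "protein"),
    annotated = seq_records(all_ids, unname(annotated), "protein"),
    baits = baits, truth = truth), class = "sim_family")
}

#' Fragment coding sequences into a synthetic contig set
#'
#' Emulates a de novo transcriptome assembly: each expressed gene emits
#' an optional guaranteed full-length contig plus `n_fragments` random
#' substrings with normally distributed lengths, each independently
#' reverse-complemented with probability 0.5. Unexpressed genes emit
#' nothing. Deterministic under `cfg$seed` (an offset stream, so it can
#' be re-run standalone).
#'
#' @param cds nucleotide [seq_records] of true coding sequences (e.g.
#'   `simulate_family(cfg)$cds`).
#' @param cfg a [sim_config].
#' @return A list: `contigs` (nucleotide [seq_records], possibly empty),
#'   `map` (data frame: `contig_id`, `gene_id`, `start`, `end` 1-based
#'   inclusive on the CDS, `strand`), `expressed` (data frame:
#'   `gene_id`, `expressed`).
#' @export
fragment_transcripts <- function(cds, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  expressed <- stats::runif(nrow(cds)) <= cfg$p_expressed
  ids <- character(0); seqs <- character(0)
  map <- list()
  for (i in seq_len(nrow(cds))) {
    if (!expressed[i]) next
    g <- cds$id[i]; s <- cds$seq[i]; len <- nchar(s)
    pieces <- list()
    if (cfg$full_length_contig)
      pieces[[length(pieces) + 1L]] <- c(1L, len)
    if (cfg$n_fragments > 0) {
      for (j in seq_len(cfg$n_fragments)) {
        flen <- round(stats::rnorm(1, cfg$frag_mean, cfg$frag_sd))
        flen <- max(min(cfg$frag_min, len), min(flen, len))
        st <- sample.int(len - flen + 1L, 1)
        pieces[[length(pieces) + 1L]] <- c(st, st + flen - 1L)
      }
    }
    for (j in seq_along(pieces)) {
      p <- pieces[[j]]
      sub <- substr(s, p[1], p[2])
      strand <- if (stats::runif(1) < 0.5) "-" else "+"
      if (strand == "-") sub <- reverse_complement(sub)
      cid <- paste0(g, "_c", j)
      ids <- c(ids, cid); seqs <- c(seqs, sub)
      map[[length(map) + 1L]] <- data.frame(
        contig_id = cid, gene_id = g, start = p[1], end = p[2],
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  contigs <- if (length(ids) == 0)
    structure(data.frame(id = character(), description = character(),
                         seq = character(), stringsAsFactors = FALSE),
              alphabet = "nucleotide",
              class = c("seq_records", "data.frame"))
  else seq_records(ids, seqs, "nucleotide")
  map <- if (length(map) == 0) data.frame(
    contig_id = character(), gene_id = character(), start = integer(),
    end = integer(), strand = character(), stringsAsFactors = FALSE)
  else do.call(rbind, map)
  list(contigs = contigs, map = map,
       expressed = data.frame(gene_id = cds$id, expressed = expressed,
                              stringsAsFactors = FALSE))
}

#' Truncate an annotated protein at one terminus
#'
#' Removes `k` residues from the N or C terminus, emulating an
#' incomplete annotation (e.g. a missing N-terminal stretch).
#'
#' @param protein protein string.
#' @param k number of residues to remove (0 < k < length).
#' @param end `"N"` or `"C"`.
#' @return The truncated protein string.
#' @export
truncate_annotation <- function(protein, k, end = c("N", "C")) {
  end <- match.arg(end)
  L <- nchar(protein)
  if (k <= 0 || k >= L)
    stop("k must satisfy 0 < k < protein length (", L, ")")
  if (end == "N") substr(protein, k + 1L, L)
  else substr(protein, 1L, L - k)
}
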