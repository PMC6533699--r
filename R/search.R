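#' Six-frame translation of a contig
#'
#' Translates a nucleotide sequence in all six reading frames (offsets
#' 0, 1, 2 on the forward strand and on the reverse complement). Minus
#' strand frames are translations of the reverse complement; their
#' coordinates are mapped back to the forward strand by
#' [frame_to_forward].
#'
#' @param seq nucleotide string (length >= 3; shorter input yields an
#'   empty result with a warning).
#' @param id contig identifier carried into the result.
#' @return A data frame with columns `contig_id`, `strand` (`"+"`/`"-"`),
#'   `offset` (0, 1, 2) and `prot`, six rows for a translatable contig.
#' @export
six_frame_translate <- function(seq, id = "contig") {
  empty <- data.frame(contig_id = character(), strand = character(),
                      offset = integer(), prot = character(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < 3) {
    warning("contig '", id, "' shorter than 3 nt; no translation")
    return(empty)
  }
  rc <- reverse_complement(seq)
  frames <- expand.grid(strand = c("+", "-"), offset = 0:2,
                        stringsAsFactors = FALSE)
  frames <- frames[order(frames$strand == "-", frames$offset), ]
  keep <- (nchar(seq) - frames$offset) >= 3
  frames <- frames[keep, , drop = FALSE]
  prot <- vapply(seq_len(nrow(frames)), function(i) {
    s <- if (frames$strand[i] == "+") seq else rc
    translate(s, frames$offset[i])
  }, character(1))
  data.frame(contig_id = id, strand = frames$strand,
             offset = as.integer(frames$offset), prot = prot,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorised six-frame translation of a whole contig set: one
# Biostrings::translate call per (strand, offset) instead of one per
# contig. Contigs shorter than 3 nt are silently dropped here (the
# public single-contig wrapper warns).
six_frame_translate_set <- function(contigs) {
  keep <- nchar(contigs$seq) >= 3
  if (!any(keep)) return(NULL)
  ids <- contigs$id[keep]
  fwd <- Biostrings::DNAStringSet(contigs$seq[keep])
  sets <- list("+" = fwd, "-" = Biostrings::reverseComplement(fwd))
  out <- list()
  for (strand in c("+", "-")) {
    s <- sets[[strand]]
    w <- Biostrings::width(s)
    for (f in 0:2) {
      ok <- (w - f) >= 3
      if (!any(ok)) next
      n_codon <- (w[ok] - f) %/% 3L
      sub <- Biostrings::subseq(s[ok], start = f + 1L,
                                end = f + 3L * n_codon)
      fuzzy <- if (any(Biostrings::alphabetFrequency(sub)[, "N"] > 0))
        "solve" else "error"
      prot <- as.character(Biostrings::translate(
        sub, no.init.codon = TRUE, if.fuzzy.codon = fuzzy))
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ids[ok], strand = strand, offset = f, prot = prot,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Map frame-translation coordinates to forward-strand nucleotides
#'
#' Converts a 1-based inclusive amino-acid interval on a frame
#' translation to the 1-based inclusive nucleotide interval on the
#' contig's forward strand. On the minus strand the interval is reported
#' with `sstart > send`, the tabular-alignment convention.
#'
#' @param aa_start,aa_end 1-based positions in the frame translation.
#' @param offset frame offset (0, 1, 2).
#' @param strand `"+"` or `"-"`.
#' @param contig_len contig length in nucleotides.
#' @return Integer vector `c(sstart, send)`.
#' @export
frame_to_forward <- function(aa_start, aa_end, offset, strand, contig_len) {
  # coding-orientation nucleotide interval of the aa range
  c1 <- offset + 3L * (aa_start - 1L) + 1L
  c2 <- offset + 3L * aa_end
  if (strand == "+") c(as.integer(c1), as.integer(c2))
  else c(as.integer(contig_len - c1 + 1L), as.integer(contig_len - c2 + 1L))
}

# Assemble an HSP table (outfmt-6 column set plus raw score, strand and
# frame offset) and apply the E-value filter and canonical sort:
# bitscore descending, E-value ascending, subject id lexicographic.
hsp_table <- function(df, evalue_cutoff) {
  df <- df[df$evalue <= evalue_cutoff, , drop = FALSE]
  df <- df[order(-df$bitscore, df$evalue, df$sseqid), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hsp_table", "data.frame")
  df
}

empty_hsps <- function() {
  hsp_table(data.frame(
    qseqid = character(), sseqid = character(), pident = numeric(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = numeric(), bitscore = numeric(),
    raw_score = integer(), strand = character(), frame_offset = integer(),
    stringsAsFactors = FALSE), Inf)
}

#' Translated search of a protein query against nucleotide contigs
#'
#' Six-frame translated local homology search (tblastn-style): the query
#' protein is Smith-Waterman-aligned to every frame translation of every
#' contig; the single best HSP per (contig, strand, frame) is scored with
#' Karlin-Altschul statistics, filtered at the E-value cutoff and sorted
#' by bitscore (descending), E-value (ascending), then contig id.
#' Subject coordinates are nucleotides on the contig's forward strand
#' (`sstart > send` on the minus strand); query coordinates are 1-based
#' residues in the query protein.
#'
#' @param query a single-row protein [seq_records] (or list with `id`,
#'   `seq`).
#' @param contigs a nucleotide [seq_records] set (non-empty).
#' @param params a [scoring_params] object.
#' @param evalue_cutoff report only HSPs with E-value at or below this
#'   (default `1e-4`, the significance criterion used throughout).
#' @return An `hsp_table` data frame (possibly zero rows).
#' @export
search <- function(query, contigs, params = scoring_params(),
                   evalue_cutoff = 1e-4) {
  stopifnot(nrow(contigs) > 0)
  frames <- six_frame_translate_set(contigs)
  if (is.null(frames) || nrow(frames) == 0) return(empty_hsps())
  db_size <- sum(nchar(frames$prot))
  qlen <- nchar(query$seq)
  a <- align_many(frames$prot, query$seq, params)
  keep <- a$score > 0
  if (!any(keep)) return(empty_hsps())
  a <- a[keep, , drop = FALSE]
  frames <- frames[keep, , drop = FALSE]
  contig_len <- stats::setNames(nchar(contigs$seq), contigs$id)
  coords <- t(vapply(seq_len(nrow(a)), function(i) {
    frame_to_forward(a$pstart[i], a$pend[i], frames$offset[i],
                     frames$strand[i], contig_len[[frames$contig_id[i]]])
  }, integer(2)))
  raw <- as.integer(round(a$score))
  bits <- bitscore(raw, params)
  hsp_table(data.frame(
    qseqid = query$id, sseqid = frames$contig_id,
    pident = round(100 * a$nmatch / a$aln_len, 2),
    length = a$aln_len, mismatch = a$nmismatch, gapopen = a$gapopen,
    qstart = a$sstart, qend = a$send,
    sstart = coords[, 1], send = coords[, 2],
    evalue = evalue(bits, qlen, db_size), bitscore = bits,
    raw_score = raw, strand = frames$strand,
    frame_offset = frames$offset,
    stringsAsFactors = FALSE, row.names = NULL), evalue_cutoff)
}

#' Reverse translated search of a contig against a protein set
#'
#' The blastx-style validation step: the contig is translated in six
#' frames and each frame is locally aligned to every reference protein.
#' Query coordinates are nucleotides on the contig's forward strand
#' (`qstart > qend` on the minus strand); subject coordinates are 1-based
#' residues in the matched protein. Reporting, filtering and ordering are
#' as in [search], with ties broken on protein id.
#'
#' @param contig a single-row nucleotide [seq_records] (or list with
#'   `id`, `seq`).
#' @param proteins a protein [seq_records] set (non-empty).
#' @inheritParams search
#' @return An `hsp_table` data frame (possibly zero rows).
#' @export
reverse_search <- function(contig, proteins, params = scoring_params(),
                           evalue_cutoff = 1e-4) {
  stopifnot(nrow(proteins) > 0)
  frames <- six_frame_translate(contig$seq, contig$id)
  if (nrow(frames) == 0) return(empty_hsps())
  db_size <- sum(nchar(proteins$seq))
  L <- nchar(contig$seq)
  out <- lapply(seq_len(nrow(frames)), function(i) {
    a <- align_many(proteins$seq, frames$prot[i], params)
    keep <- a$score > 0
    if (!any(keep)) return(NULL)
    a <- a[keep, , drop = FALSE]
    prot_ids <- proteins$id[keep]
    coords <- t(vapply(seq_len(nrow(a)), function(j) {
      frame_to_forward(a$sstart[j], a$send[j], frames$offset[i],
                       frames$strand[i], L)
    }, integer(2)))
    raw <- as.integer(round(a$score))
    bits <- bitscore(raw, params)
    data.frame(
      qseqid = contig$id, sseqid = prot_ids,
      pident = round(100 * a$nmatch / a$aln_len, 2),
      length = a$aln_len, mismatch = a$nmismatch, gapopen = a$gapopen,
      qstart = coords[, 1], qend = coords[, 2],
      sstart = a$pstart, send = a$pend,
      evalue = evalue(bits, nchar(frames$prot[i]), db_size),
      bitscore = bits, raw_score = raw, strand = frames$strand[i],
      frame_offset = frames$offset[i],
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) return(empty_hsps())
  hsp_table(out, evalue_cutoff)
}

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Write an HSP table in 12-column tabular (outfmt-6 dialect) format
#'
#' Percent identity is written with two decimals, bitscore with one, and
#' the E-value with three significant digits, so that writing, reading
#' and re-writing reproduces the file byte for byte.
#'
#' @param hsps an `hsp_table` or data frame with the 12 standard columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outfmt6 <- function(hsps, path) {
  lines <- vapply(seq_len(nrow(hsps)), function(i) {
    paste(hsps$qseqid[i], hsps$sseqid[i],
          sprintf("%.2f", hsps$pident[i]), hsps$length[i],
          hsps$mismatch[i], hsps$gapopen[i], hsps$qstart[i], hsps$qend[i],
          hsps$sstart[i], hsps$send[i],
          sprintf("%.3g", hsps$evalue[i]),
          sprintf("%.1f", hsps$bitscore[i]), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 12-column tabular (outfmt-6 dialect) alignment file
#'
#' Accepts the plug-in path for externally computed alignments (e.g. from
#' BLAST+ with `-outfmt 6`). Extra trailing columns are tolerated and
#' dropped.
#'
#' @param path path to a tab-separated alignment table without header.
#' @return An `hsp_table` data frame with the 12 standard columns.
#' @export
read_outfmt6 <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected at least 12 tab-separated columns")
  df <- df[, 1:12]
  names(df) <- OUTFMT6_COLS
  df$pident <- as.numeric(df$pident)
  df$evalue <- as.numeric(df$evalue)
  df$bitscore <- as.numeric(df$bitscore)
  for (col in c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send"))
    df[[col]] <- as.integer(df[[col]])
  class(df) <- c("hsp_table", "data.frame")
  df
}
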