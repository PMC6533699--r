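#' Find open reading frames on a contig
#'
#' Scans all six reading frames. Complete ORFs run from the first ATG of
#' a stop-delimited segment to the stop codon (inclusive); 5'-partial
#' ORFs (no ATG before the frame's first stop) run from the frame start
#' to that stop; 3'-partial ORFs (ATG with no downstream stop) run from
#' the ATG to the frame end. Nested internal ATGs are not reported
#' separately. Coordinates are 0-based half-open on the forward strand;
#' `nuc_seq` is in coding orientation and includes the stop codon when
#' one exists; `protein` never contains `*`.
#'
#' @param contig a single-row nucleotide [seq_records] (or list with
#'   `id`, `seq`).
#' @param min_aa minimum protein length in residues (default 100,
#'   the conventional long-ORF cutoff; configurable down to 1).
#' @param include_partial report 5'-/3'-partial ORFs (default TRUE:
#'   assembly contigs do not necessarily span whole transcripts).
#' @return A data frame of class `orf_table` with columns `contig_id`,
#'   `strand`, `frame_offset`, `start`, `end`, `nuc_seq`, `protein`,
#'   `partial` (`"complete"`, `"5prime"`, `"3prime"`) and `aa_len`,
#'   sorted by protein length descending.
#' @export
find_orfs <- function(contig, min_aa = 100L, include_partial = TRUE) {
  L <- nchar(contig$seq)
  stopifnot(L >= 3)
  rc <- reverse_complement(contig$seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig$seq else rc
    for (f in 0:2) {
      if (L - f < 3) next
      prot <- translate(s, f)
      n <- nchar(prot)
      chars <- strsplit(prot, "")[[1]]
      stops <- which(chars == "*")
      seg_starts <- c(1L, stops + 1L)
      seg_ends <- c(stops - 1L, n)
      for (k in seq_along(seg_starts)) {
        a <- seg_starts[k]; b <- seg_ends[k]
        if (a > b) next
        has_stop <- k <= length(stops)
        ms <- which(chars[a:b] == "M")
        if (length(ms) > 0) {
          m <- a + ms[1] - 1L
          aa1 <- m; aa2 <- b
          partial <- if (has_stop) "complete" else "3prime"
        } else if (a == 1L && has_stop) {
          aa1 <- 1L; aa2 <- b
          partial <- "5prime"
        } else next
        aa_len <- aa2 - aa1 + 1L
        if (aa_len < min_aa) next
        if (!include_partial && partial != "complete") next
        # coding-orientation nucleotide interval, stop codon included
        last_codon <- if (has_stop) aa2 + 1L else aa2
        c1 <- f + 3L * (aa1 - 1L) + 1L
        c2 <- f + 3L * last_codon
        if (strand == "+") { st0 <- c1 - 1L; en0 <- c2 }
        else { st0 <- L - c2; en0 <- L - c1 + 1L }
        rows[[length(rows) + 1L]] <- list(
          strand = strand, frame_offset = f, start = st0, end = en0,
          nuc_seq = substr(s, c1, c2), protein = substr(prot, aa1, aa2),
          partial = partial, aa_len = aa_len)
      }
    }
  }
  out <- if (length(rows) == 0) data.frame(
    contig_id = character(), strand = character(),
    frame_offset = integer(), start = integer(), end = integer(),
    nuc_seq = character(), protein = character(), partial = character(),
    aa_len = integer(), stringsAsFactors = FALSE)
  else data.frame(
    contig_id = contig$id,
    strand = vapply(rows, `[[`, character(1), "strand"),
    frame_offset = vapply(rows, `[[`, integer(1), "frame_offset"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    nuc_seq = vapply(rows, `[[`, character(1), "nuc_seq"),
    protein = vapply(rows, `[[`, character(1), "protein"),
    partial = vapply(rows, `[[`, character(1), "partial"),
    aa_len = vapply(rows, `[[`, integer(1), "aa_len"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$aa_len, out$partial != "complete",
                   out$strand == "-", out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("orf_table", "data.frame")
  out
}

#' Select a contig's longest ORF as its protein representation
#'
#' Ties are broken in favour of complete over partial ORFs, plus strand
#' over minus, then smaller forward-strand start.
#'
#' @inheritParams find_orfs
#' @param partial_eligible may a partial ORF be selected (default TRUE)?
#' @return A one-row `orf_table`, or `NULL` when no ORF passes `min_aa`.
#' @export
longest_orf <- function(contig, min_aa = 100L, partial_eligible = TRUE) {
  orfs <- find_orfs(contig, min_aa = min_aa,
                    include_partial = partial_eligible)
  if (nrow(orfs) == 0) return(NULL)
  orfs[1, , drop = FALSE]
}

#' Write ORF coordinates as BED
#'
#' Six-column BED: 0-based half-open forward-strand interval, ORF name
#' (`contig:start-end`), score 0, strand.
#'
#' @param orfs an `orf_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orf_bed <- function(orfs, path) {
  lines <- vapply(seq_len(nrow(orfs)), function(i) {
    paste(orfs$contig_id[i], orfs$start[i], orfs$end[i],
          sprintf("%s:%d-%d", orfs$contig_id[i], orfs$start[i],
                  orfs$end[i]),
          0L, orfs$strand[i], sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
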