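# Independent reference implementations used as test oracles. These are
# deliberately written as plain, unoptimised R and never call the
# package's alignment or ORF code paths.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NTS <- c("A", "C", "G", "T")

rand_prot <- function(n) paste(sample(AAS, n, replace = TRUE),
                               collapse = "")
rand_nuc <- function(n) paste(sample(NTS, n, replace = TRUE),
                              collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Affine-gap dynamic programming (Gotoh), plain matrices. A gap of
# length k costs go + k * ge. type = "local" returns the best
# Smith-Waterman score (>= 0); type = "global" the end-to-end
# Needleman-Wunsch score with end gaps penalised.
oracle_align_score <- function(q, s, mat = blosum62, go = 11, ge = 1,
                               type = c("local", "global")) {
  type <- match.arg(type)
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  qi <- match(qc, rownames(mat))
  si <- match(sc, colnames(mat))
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # last column aligned pair
  X <- matrix(NEG, n + 1, m + 1)  # gap in s (consumes q)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in q (consumes s)
  if (type == "local") {
    M[, 1] <- 0; M[1, ] <- 0
  } else {
    M[1, 1] <- 0
    for (i in 2:(n + 1)) X[i, 1] <- -(go + (i - 1) * ge)
    for (j in 2:(m + 1)) Y[1, j] <- -(go + (j - 1) * ge)
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- mat[qi[i - 1], si[j - 1]]
      best_prev <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- best_prev + sub
      if (type == "local") M[i, j] <- max(M[i, j], sub, 0)
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    }
  }
  if (type == "local") max(0, max(M)) else max(M[n + 1, m + 1],
                                               X[n + 1, m + 1],
                                               Y[n + 1, m + 1])
}

# Plain-R reverse complement and codon-table translation, so the
# translated-search oracle shares no code with the package.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
        collapse = "")
}
oracle_translate <- function(s, f) {
  gc <- Biostrings::GENETIC_CODE
  n_codon <- (nchar(s) - f) %/% 3L
  paste(unname(gc[substring(s, f + seq(1L, by = 3L,
                                       length.out = n_codon),
                            f + seq(3L, by = 3L,
                                    length.out = n_codon))]),
        collapse = "")
}

# Best translated-search raw score per (contig, strand, offset): an
# exhaustive enumeration over the six frames using the DP oracle.
oracle_frame_scores <- function(query_seq, contig_seq, contig_id) {
  out <- list()
  rc <- oracle_revcomp(contig_seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig_seq else rc
    for (f in 0:2) {
      if (nchar(s) - f < 3) next
      prot <- oracle_translate(s, f)
      sc <- oracle_align_score(prot, query_seq, type = "local")
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contig_id, strand = strand, offset = f,
        score = sc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Independent ORF scan: codon-by-codon state machine per frame, using
# the genetic code table directly (never the package's scanner).
oracle_orf_scan <- function(seq, id, min_aa = 1L) {
  gc <- Biostrings::GENETIC_CODE
  L <- nchar(seq)
  rc <- orthrefine::reverse_complement(seq)
  rows <- list()
  emit <- function(strand, f, aa1, aa2, has_stop, partial, aas, s) {
    aa_len <- aa2 - aa1 + 1L
    if (aa_len < min_aa) return()
    last <- if (has_stop) aa2 + 1L else aa2
    c1 <- f + 3L * (aa1 - 1L) + 1L
    c2 <- f + 3L * last
    st0 <- if (strand == "+") c1 - 1L else L - c2
    en0 <- if (strand == "+") c2 else L - c1 + 1L
    rows[[length(rows) + 1L]] <<- list(
      contig_id = id, strand = strand, frame_offset = f, start = st0,
      end = en0, nuc_seq = substr(s, c1, c2),
      protein = paste(aas[aa1:aa2], collapse = ""), partial = partial,
      aa_len = aa_len)
  }
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (f in 0:2) {
      n_codon <- (L - f) %/% 3L
      if (n_codon < 1) next
      codons <- substring(s, f + seq(1L, by = 3L, length.out = n_codon),
                          f + seq(3L, by = 3L, length.out = n_codon))
      aas <- unname(gc[codons])
      atg <- NA_integer_   # first ATG since the last stop
      seg_start <- 1L      # first codon of the current segment
      for (i in seq_len(n_codon)) {
        if (aas[i] == "*") {
          if (!is.na(atg)) emit(strand, f, atg, i - 1L, TRUE,
                                "complete", aas, s)
          else if (seg_start == 1L && i > 1L)
            emit(strand, f, 1L, i - 1L, TRUE, "5prime", aas, s)
          atg <- NA_integer_
          seg_start <- i + 1L
        } else if (is.na(atg) && codons[i] == "ATG") {
          atg <- i
        }
      }
      if (!is.na(atg)) emit(strand, f, atg, n_codon, FALSE, "3prime",
                            aas, s)
    }
  }
  out <- if (length(rows) == 0) data.frame(
    contig_id = character(), strand = character(),
    frame_offset = integer(), start = integer(), end = integer(),
    nuc_seq = character(), protein = character(), partial = character(),
    aa_len = integer(), stringsAsFactors = FALSE)
  else data.frame(
    contig_id = vapply(rows, `[[`, character(1), "contig_id"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    frame_offset = vapply(rows, `[[`, integer(1), "frame_offset"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    nuc_seq = vapply(rows, `[[`, character(1), "nuc_seq"),
    protein = vapply(rows, `[[`, character(1), "protein"),
    partial = vapply(rows, `[[`, character(1), "partial"),
    aa_len = vapply(rows, `[[`, integer(1), "aa_len"),
    stringsAsFactors = FALSE)
  out <- out[order(out$strand, out$frame_offset, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonicalise an ORF table for comparison with the oracle.
sort_orfs <- function(orfs) {
  df <- as.data.frame(orfs)[, c("contig_id", "strand", "frame_offset",
                                "start", "end", "nuc_seq", "protein",
                                "partial", "aa_len")]
  df <- df[order(df$strand, df$frame_offset, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random in-frame coding stretch: n sense (non-stop) codons.
rand_nuc_codons <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# Random record sets for FASTA round-trip properties.
rand_records <- function(n, alphabet = "nucleotide") {
  ids <- sprintf("r%04d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i) {
    if (alphabet == "nucleotide") rand_nuc(sample(10:200, 1))
    else rand_prot(sample(10:200, 1))
  }, character(1))
  desc <- ifelse(seq_len(n) %% 3 == 0, paste("desc", ids), "")
  orthrefine::seq_records(ids, seqs, alphabet, desc)
}
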