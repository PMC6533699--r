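# Alphabets. Nucleotide records are normalised to {A,C,G,T,N} on ingest;
# protein records allow the 20 standard residues plus X and a single
# trailing stop '*'.
NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PROT_ALPHABET <- c(AA20, "X", "*")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a set of identified sequence records
#'
#' A `seq_records` object is the package's basic container for FASTA
#' records: a data frame with columns `id`, `description` and `seq`, plus
#' an `alphabet` attribute (`"nucleotide"` or `"protein"`). Sequences are
#' uppercased and validated against the alphabet on construction;
#' nucleotide `U` is mapped to `T` and other IUPAC ambiguity codes to `N`
#' (with a warning), since real assemblies contain them.
#'
#' @param id character vector of record identifiers (no whitespace).
#' @param seq character vector of sequences, same length as `id`.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param description optional character vector of free-text descriptions.
#' @return A data frame of class `seq_records`.
#' @export
seq_records <- function(id, seq, alphabet = c("nucleotide", "protein"),
                        description = "") {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  seq <- as.character(seq)
  stopifnot(length(id) == length(seq))
  description <- rep_len(as.character(description), length(id))
  if (any(grepl("[[:space:]]", id)))
    stop("record ids must not contain whitespace")
  dup <- id[duplicated(id)]
  if (length(dup) > 0)
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  seq <- vapply(seq_along(seq), function(i) {
    normalise_seq(seq[i], alphabet, id[i])
  }, character(1))
  structure(
    data.frame(id = id, description = description, seq = seq,
               stringsAsFactors = FALSE),
    alphabet = alphabet, class = c("seq_records", "data.frame")
  )
}

# Uppercase and validate one sequence; errors name the record and the
# 1-based position of the first offending character.
normalise_seq <- function(s, alphabet, id) {
  s <- toupper(s)
  if (nchar(s) == 0L)
    stop("record '", id, "': empty sequence")
  if (alphabet == "nucleotide") {
    s <- gsub("U", "T", s, fixed = TRUE)
    chars <- strsplit(s, "")[[1]]
    ambig <- chars %in% IUPAC_AMBIG
    if (any(ambig)) {
      warning("record '", id, "': ", sum(ambig),
              " IUPAC ambiguity code(s) mapped to N")
      chars[ambig] <- "N"
      s <- paste(chars, collapse = "")
    }
    bad <- which(!chars %in% NUC_ALPHABET)
    if (length(bad) > 0)
      stop("record '", id, "': invalid nucleotide character '",
           chars[bad[1]], "' at position ", bad[1])
  } else {
    chars <- strsplit(s, "")[[1]]
    bad <- which(!chars %in% PROT_ALPHABET)
    if (length(bad) > 0)
      stop("record '", id, "': invalid amino-acid character '",
           chars[bad[1]], "' at position ", bad[1])
    stars <- which(chars == "*")
    if (length(stars) > 1 || (length(stars) == 1 && stars != length(chars)))
      stop("record '", id, "': '*' only allowed as a single trailing stop")
  }
  s
}

#' Read a FASTA file into a validated record set
#'
#' Headers are split at the first whitespace into `id` and `description`;
#' sequence lines are concatenated and uppercased. Duplicate ids,
#' characters outside the alphabet, and empty files are errors.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A [seq_records] data frame, record order preserved.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  id <- sub("[[:space:]].*$", "", headers)
  description <- ifelse(grepl("[[:space:]]", headers),
                        sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  seq_records(id, as.character(set), alphabet, description)
}

#' Write a record set as FASTA
#'
#' Round-trips with [read_fasta]: reading the written file reproduces the
#' records exactly.
#'
#' @param records a [seq_records] object (non-empty).
#' @param path output path.
#' @param wrap line width for sequence wrapping (positive integer).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(nrow(records) > 0, wrap >= 1)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[i]))
      paste(records$id[i], records$description[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' `N` complements to `N`; the operation is an involution.
#'
#' @param seq a nucleotide string over `{A,C,G,T,N}` (case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("invalid nucleotide character in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a nucleotide sequence in a given frame offset
#'
#' Standard genetic code (translation table 1). Stops render as `*`;
#' codons containing `N` render as the unambiguous amino acid when all
#' codon completions agree, otherwise `X`. A trailing partial codon is
#' dropped, so the output has `floor((nchar(seq) - offset)/3)` residues.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @param offset reading-frame offset, 0, 1 or 2.
#' @return The protein string.
#' @export
translate <- function(seq, offset = 0L) {
  seq <- toupper(seq)
  stopifnot(offset %in% 0:2)
  n_codon <- (nchar(seq) - offset) %/% 3L
  if (n_codon < 1L)
    stop("sequence too short to translate at offset ", offset)
  sub <- substr(seq, offset + 1L, offset + 3L * n_codon)
  # "solve" renders N codons as X unless every completion agrees, but
  # building the fuzzy code table is costly; skip it when N-free
  fuzzy <- if (grepl("N", sub, fixed = TRUE)) "solve" else "error"
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = fuzzy))
}
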