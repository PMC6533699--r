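#' Scoring parameters for protein alignment and E-value statistics
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw Smith-Waterman scores
#' into bitscores and E-values. Defaults are the published values for
#' gapped BLOSUM62 with gap open 11 / extend 1 (lambda = 0.267,
#' K = 0.041). A gap of length k costs `gap_open + k * gap_extend`.
#'
#' @param matrix substitution matrix name (one of the matrices shipped
#'   with Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM80"`, `"PAM250"`).
#' @param gap_open,gap_extend positive gap penalties.
#' @param lambda,K Karlin-Altschul parameters (positive).
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0, gap_open > 0, gap_extend > 0)
  mat <- tryCatch({
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  }, warning = function(w) stop("unknown substitution matrix: ", matrix),
     error = function(e) stop("unknown substitution matrix: ", matrix))
  structure(list(matrix_name = matrix, matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_params")
}

# Vectorised core aligner: many pattern strings against one subject.
# type "local" (Smith-Waterman) or "global" (Needleman-Wunsch with end
# gaps penalised). Returns one row per pattern with score, 1-based
# coordinates and match/mismatch/gap-open counts; the aligned strings
# are extracted only on request (costly for large pattern sets).
align_many <- function(patterns, subject, params, type = "local",
                       strings = FALSE) {
  pat <- Biostrings::AAStringSet(patterns)
  aln <- Biostrings::pairwiseAlignment(
    pat, Biostrings::AAString(subject), type = type,
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  ins <- Biostrings::insertion(Biostrings::nindel(aln))
  del <- Biostrings::deletion(Biostrings::nindel(aln))
  pstart <- Biostrings::start(Biostrings::pattern(aln))
  pend <- Biostrings::end(Biostrings::pattern(aln))
  data.frame(
    score = Biostrings::score(aln),
    pstart = pstart, pend = pend,
    sstart = Biostrings::start(Biostrings::subject(aln)),
    send = Biostrings::end(Biostrings::subject(aln)),
    nmatch = Biostrings::nmatch(aln),
    nmismatch = Biostrings::nmismatch(aln),
    gapopen = ins[, "Length"] + del[, "Length"],
    # columns = pattern span + gap positions in the pattern row
    aln_len = (pend - pstart + 1L) + del[, "WidthSum"],
    p_aln = if (strings)
      as.character(Biostrings::alignedPattern(aln)) else NA_character_,
    s_aln = if (strings)
      as.character(Biostrings::alignedSubject(aln)) else NA_character_,
    stringsAsFactors = FALSE)
}

#' Smith-Waterman local alignment of two protein strings
#'
#' Affine-gap local alignment under the given scoring parameters. The raw
#' score is the sum of substitution-matrix scores over aligned pairs minus
#' `gap_open + k * gap_extend` per length-k gap; a score of 0 means no
#' positive-scoring local alignment exists and the alignment is empty.
#'
#' @param q,s non-empty protein strings (may contain `*` from translated
#'   frames; `*` scores through its matrix column).
#' @param params a [scoring_params] object.
#' @return A list with `raw_score`, aligned strings `q_aln`/`s_aln`, and
#'   1-based inclusive coordinates `qstart`, `qend`, `sstart`, `send`
#'   (all 0/empty when no positive alignment exists).
#' @export
local_align <- function(q, s, params = scoring_params()) {
  stopifnot(nchar(q) > 0, nchar(s) > 0)
  r <- align_many(s, q, params, type = "local", strings = TRUE)
  if (r$score[1] <= 0)
    return(list(raw_score = 0L, q_aln = "", s_aln = "",
                qstart = 0L, qend = 0L, sstart = 0L, send = 0L))
  list(raw_score = as.integer(round(r$score[1])),
       q_aln = r$s_aln[1], s_aln = r$p_aln[1],
       qstart = r$sstart[1], qend = r$send[1],
       sstart = r$pstart[1], send = r$pend[1])
}

#' Bitscore from a raw alignment score
#'
#' `(lambda * raw_score - ln K) / ln 2`, the Karlin-Altschul normalised
#' score in bits.
#'
#' @param raw_score non-negative raw alignment score(s).
#' @param params a [scoring_params] object supplying `lambda` and `K`.
#' @return Numeric bitscore(s).
#' @export
bitscore <- function(raw_score, params = scoring_params()) {
  stopifnot(all(raw_score >= 0))
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' E-value from a bitscore and search-space size
#'
#' Expected number of chance alignments scoring at least this well in a
#' search space of `query_len * db_size` residue pairs:
#' `query_len * db_size * 2^(-bitscore)`.
#'
#' @param bits bitscore(s).
#' @param query_len query length in residues (positive).
#' @param db_size total residues in the (translated) database (positive).
#' @return Numeric E-value(s).
#' @export
evalue <- function(bits, query_len, db_size) {
  stopifnot(query_len > 0, db_size > 0)
  query_len * db_size * 2^(-bits)
}
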