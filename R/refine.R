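#' Query coverage of an alignment
#'
#' Fraction of the query protein spanned by the alignment, computed from
#' the alignment start and end positions in the query and the query's
#' length: `100 * (qend - qstart + 1) / qlen`.
#'
#' @param qstart,qend 1-based inclusive alignment bounds in the query.
#' @param qlen query length in residues.
#' @return Percentage in (0, 100].
#' @export
query_coverage <- function(qstart, qend, qlen) {
  if (!(all(qstart >= 1) && all(qstart <= qend) && all(qend <= qlen)))
    stop("require 1 <= qstart <= qend <= qlen")
  100 * (qend - qstart + 1) / qlen
}

#' Directional pairwise sequence identities
#'
#' Global (end-to-end, affine-gap, end gaps penalised) alignment of two
#' proteins; identical aligned residue pairs are counted and expressed as
#' a percentage of each full ungapped sequence length, the orthology-
#' database convention: `id_wrt_a` is the percent of `a` matching `b`
#' and vice versa. The aligned-columns identity (`pct_identity_aln`) is
#' also reported for tabular-format compatibility.
#'
#' @param a,b non-empty protein strings.
#' @param params a [scoring_params] object.
#' @return A list of class `pairwise_identity` with `matches`,
#'   `aln_cols`, `id_wrt_a`, `id_wrt_b`, `pct_identity_aln`.
#' @export
pairwise_identity <- function(a, b, params = scoring_params()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  r <- align_many(b, a, params, type = "global")
  structure(list(
    matches = r$nmatch[1], aln_cols = r$aln_len[1],
    id_wrt_a = 100 * r$nmatch[1] / nchar(a),
    id_wrt_b = 100 * r$nmatch[1] / nchar(b),
    pct_identity_aln = 100 * r$nmatch[1] / r$aln_len[1]),
    class = "pairwise_identity")
}

#' Quantify a refinement against the orthologous bait
#'
#' When an annotated target sequence exists, the refinement is the
#' decrease in the absolute difference of the two directional identities
#' (target-vs-bait) achieved by replacing the old annotation with the
#' refined sequence; a large difference signals a length discrepancy,
#' and a successful refinement drives it towards zero. When no
#' annotation exists, the fallback compares, from a local alignment of
#' refined vs bait, the percentage of each sequence covered by the
#' alignment.
#'
#' @param bait a single-row protein [seq_records] (or list `id`, `seq`):
#'   the well-annotated orthologous protein.
#' @param refined the assembly-derived candidate protein (same shape).
#' @param old_target the existing annotated target, or `NULL`.
#' @param params a [scoring_params] object.
#' @return A list of class `refinement_report`. In identity mode:
#'   `old_identity` / `refined_identity` ([pairwise_identity] objects),
#'   signed and absolute identity differences for each, and
#'   `delta_identity` (the decrease, old minus refined absolute
#'   difference). In coverage mode: `coverage_refined`, `coverage_bait`,
#'   their signed and absolute difference.
#' @export
refinement_delta <- function(bait, refined, old_target = NULL,
                             params = scoring_params()) {
  stopifnot(nchar(bait$seq) > 0, nchar(refined$seq) > 0)
  rep <- list(bait_id = bait$id, refined_id = refined$id)
  if (!is.null(old_target)) {
    old_pi <- pairwise_identity(old_target$seq, bait$seq, params)
    new_pi <- pairwise_identity(refined$seq, bait$seq, params)
    rep$mode <- "identity"
    rep$old_target_id <- old_target$id
    rep$old_identity <- old_pi
    rep$refined_identity <- new_pi
    rep$old_diff <- old_pi$id_wrt_a - old_pi$id_wrt_b
    rep$refined_diff <- new_pi$id_wrt_a - new_pi$id_wrt_b
    rep$old_abs_diff <- abs(rep$old_diff)
    rep$refined_abs_diff <- abs(rep$refined_diff)
    rep$delta_identity <- rep$old_abs_diff - rep$refined_abs_diff
  } else {
    aln <- local_align(bait$seq, refined$seq, params)
    rep$mode <- "coverage"
    if (aln$raw_score == 0) {
      rep$coverage_refined <- 0
      rep$coverage_bait <- 0
    } else {
      rep$coverage_refined <- query_coverage(aln$sstart, aln$send,
                                             nchar(refined$seq))
      rep$coverage_bait <- query_coverage(aln$qstart, aln$qend,
                                          nchar(bait$seq))
    }
    rep$coverage_diff <- rep$coverage_refined - rep$coverage_bait
    rep$coverage_abs_diff <- abs(rep$coverage_diff)
  }
  class(rep) <- "refinement_report"
  rep
}

#' Center-star multiple sequence alignment
#'
#' Small progressive MSA for visual assessment of refinement success:
#' the sequence with the maximal summed pairwise global score is the
#' center; every other sequence is aligned to it and merged under "once
#' a gap, always a gap". All output rows have equal length and ungap to
#' their inputs exactly. For publication-grade alignments export the
#' unaligned sequences and use a dedicated MSA tool.
#'
#' @param records a protein [seq_records] with at least two rows.
#' @param params a [scoring_params] object.
#' @return A named character vector of aligned rows (gap `-`), in input
#'   order.
#' @export
center_star_msa <- function(records, params = scoring_params()) {
  n <- nrow(records)
  if (is.null(n) || n < 2) stop("center-star MSA needs >= 2 sequences")
  seqs <- records$seq
  ids <- records$id
  # summed pairwise global score per sequence
  sums <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sc <- align_many(seqs[j], seqs[i], params, type = "global")$score[1]
    sums[i] <- sums[i] + sc
    sums[j] <- sums[j] + sc
  }
  center <- which.max(sums)
  others <- setdiff(seq_len(n), center)
  master <- strsplit(seqs[center], "")[[1]]  # center row with gaps
  rows <- list()                             # aligned non-center rows
  for (k in others) {
    a <- align_many(seqs[k], seqs[center], params, type = "global",
                    strings = TRUE)
    c_aln <- strsplit(a$s_aln[1], "")[[1]]   # center in pairwise aln
    o_aln <- strsplit(a$p_aln[1], "")[[1]]   # other in pairwise aln
    # merge pairwise alignment into master ("once a gap, always a gap")
    new_master <- character(0); new_o <- character(0)
    ins_old <- integer(0)  # columns inserted into existing rows
    i <- 1L; j <- 1L
    while (i <= length(master) || j <= length(c_aln)) {
      mi <- if (i <= length(master)) master[i] else NA
      cj <- if (j <= length(c_aln)) c_aln[j] else NA
      if (!is.na(mi) && mi == "-" && (is.na(cj) || cj != "-")) {
        # master-only gap column: pad the new row
        new_master <- c(new_master, "-"); new_o <- c(new_o, "-")
        i <- i + 1L
      } else if (!is.na(cj) && cj == "-" && (is.na(mi) || mi != "-")) {
        # new gap in center: insert a column into all existing rows
        new_master <- c(new_master, "-"); new_o <- c(new_o, o_aln[j])
        ins_old <- c(ins_old, length(new_master))
        j <- j + 1L
      } else {
        new_master <- c(new_master, mi); new_o <- c(new_o, o_aln[j])
        i <- i + 1L; j <- j + 1L
      }
    }
    if (length(ins_old) > 0) {
      rows <- lapply(rows, function(r) {
        out <- character(length(new_master))
        keep <- setdiff(seq_along(new_master), ins_old)
        out[ins_old] <- "-"
        out[keep] <- r
        out
      })
    }
    master <- new_master
    rows[[as.character(k)]] <- new_o
  }
  aligned <- vector("list", n)
  aligned[[center]] <- master
  for (k in others) aligned[[k]] <- rows[[as.character(k)]]
  out <- vapply(aligned, paste, character(1), collapse = "")
  names(out) <- ids
  out
}

#' Write an alignment (or any named sequences) as FASTA
#'
#' @param aln named character vector, e.g. from [center_star_msa].
#' @param path output path.
#' @param wrap line width.
#' @return `path`, invisibly.
#' @export
write_aln_fasta <- function(aln, path, wrap = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln)) {
    writeLines(paste0(">", names(aln)[i]), con)
    s <- aln[[i]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}
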