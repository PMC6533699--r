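#' Select the n best-matching contigs from a forward search
#'
#' Orders HSPs by bitscore (descending), E-value (ascending), contig id,
#' and returns the first `n` distinct contig ids; fewer when fewer
#' distinct contigs hit.
#'
#' @param hsps an `hsp_table` from [search].
#' @param n number of contigs to keep (default 1).
#' @return Character vector of contig ids (possibly shorter than `n`).
#' @export
best_contigs <- function(hsps, n = 1L) {
  if (nrow(hsps) == 0) return(character(0))
  hsps <- hsps[order(-hsps$bitscore, hsps$evalue, hsps$sseqid), ,
               drop = FALSE]
  ids <- unique(hsps$sseqid)
  ids[seq_len(min(n, length(ids)))]
}

#' Reciprocal best-hit validation of a bait protein
#'
#' Forward translated search of the bait against the contigs, selection
#' of the `n` best contigs, then a reverse search of each selected contig
#' against the reference proteome. The bait is a reciprocal best hit
#' when the top-ranked contig's reverse top hit is the bait itself
#' (matched on exact sequence id). In `"whole_contig"` mode the reverse
#' query is the full contig (six-frame); in `"longest_orf"` mode it is
#' the contig's longest-ORF protein.
#'
#' @param bait a single-row protein [seq_records] (or list `id`, `seq`).
#' @param contigs nucleotide [seq_records] database.
#' @param reference_proteins protein [seq_records]; must contain the
#'   bait's own id.
#' @param params a [scoring_params] object.
#' @param n number of best contigs to carry into the reverse step.
#' @param evalue_cutoff significance cutoff for both directions.
#' @param reverse_mode `"whole_contig"` (default) or `"longest_orf"`.
#' @param min_aa longest-ORF cutoff used in `"longest_orf"` mode.
#' @return A list of class `rbh_result`: `bait_id`, `best_contig_ids`,
#'   `forward` (HSP table), `reverse_top` (named character, top reverse
#'   hit per selected contig, `NA` when none), `reverse` (list of HSP
#'   tables), `is_rbh`, `reverse_mode`.
#' @export
reciprocal_best_hit <- function(bait, contigs, reference_proteins,
                                params = scoring_params(), n = 1L,
                                evalue_cutoff = 1e-4,
                                reverse_mode = c("whole_contig",
                                                 "longest_orf"),
                                min_aa = 100L) {
  reverse_mode <- match.arg(reverse_mode)
  if (!bait$id %in% reference_proteins$id)
    stop("bait '", bait$id, "' absent from the reference protein set")
  fwd <- search(bait, contigs, params, evalue_cutoff)
  best <- best_contigs(fwd, n)
  rev_top <- stats::setNames(rep(NA_character_, length(best)), best)
  rev_list <- stats::setNames(vector("list", length(best)), best)
  for (cid in best) {
    contig <- contigs[contigs$id == cid, , drop = FALSE]
    rev <- if (reverse_mode == "whole_contig") {
      reverse_search(contig, reference_proteins, params, evalue_cutoff)
    } else {
      orf <- longest_orf(contig, min_aa = min_aa)
      if (is.null(orf)) empty_hsps()
      else search_protein(list(id = cid, seq = orf$protein),
                          reference_proteins, params, evalue_cutoff)
    }
    rev_list[[cid]] <- rev
    if (nrow(rev) > 0) rev_top[cid] <- rev$sseqid[1]
  }
  structure(list(
    bait_id = bait$id, best_contig_ids = best, forward = fwd,
    reverse_top = rev_top, reverse = rev_list,
    is_rbh = length(best) > 0 && !is.na(rev_top[best[1]]) &&
      rev_top[best[1]] == bait$id,
    reverse_mode = reverse_mode), class = "rbh_result")
}

# Protein-vs-protein search used by the longest-ORF reverse mode: the
# ORF peptide is locally aligned to every reference protein and hits are
# reported with the same statistics and ordering as the translated
# searches.
search_protein <- function(query, proteins, params = scoring_params(),
                           evalue_cutoff = 1e-4) {
  stopifnot(nrow(proteins) > 0)
  db_size <- sum(nchar(proteins$seq))
  a <- align_many(proteins$seq, query$seq, params)
  keep <- a$score > 0
  if (!any(keep)) return(empty_hsps())
  a <- a[keep, , drop = FALSE]
  ids <- proteins$id[keep]
  raw <- as.integer(round(a$score))
  bits <- bitscore(raw, params)
  hsp_table(data.frame(
    qseqid = query$id, sseqid = ids,
    pident = round(100 * a$nmatch / a$aln_len, 2),
    length = a$aln_len, mismatch = a$nmismatch, gapopen = a$gapopen,
    qstart = a$sstart, qend = a$send, sstart = a$pstart, send = a$pend,
    evalue = evalue(bits, nchar(query$seq), db_size), bitscore = bits,
    raw_score = raw, strand = "+", frame_offset = 0L,
    stringsAsFactors = FALSE, row.names = NULL), evalue_cutoff)
}

#' Reciprocal best-hit detection rate
#'
#' Percentage of baits validated as reciprocal best hits.
#'
#' @param results list of `rbh_result` objects.
#' @param total_baits total number of baits searched (>= number of RBH).
#' @return Percentage in \code{[0, 100]}.
#' @export
detection_rate <- function(results, total_baits) {
  if (total_baits == 0) stop("total_baits must be positive")
  n_rbh <- sum(vapply(results, function(r) isTRUE(r$is_rbh), logical(1)))
  if (total_baits < n_rbh) stop("total_baits smaller than RBH count")
  100 * n_rbh / total_baits
}

#' Exclusive intersection-region counts across named id sets
#'
#' For every non-empty subset of set names, counts the elements belonging
#' to exactly those sets (UpSet semantics), so the region counts
#' partition the union.
#'
#' @param sets named list (>= 2) of character id vectors.
#' @return A list with `regions` (data frame: `region`, `degree`,
#'   `count`), `set_sizes`, and `union_size`.
#' @export
rbh_set_summary <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, nm))
  key <- apply(member, 1, function(x) paste(nm[x], collapse = "&"))
  counts <- table(key)
  # enumerate all non-empty subsets in a stable order
  subsets <- unlist(lapply(seq_along(nm), function(k) {
    combn(nm, k, paste, collapse = "&", simplify = FALSE)
  }))
  regions <- data.frame(
    region = unlist(subsets),
    degree = lengths(gregexpr("&", unlist(subsets), fixed = TRUE)) + 1L,
    count = as.integer(ifelse(unlist(subsets) %in% names(counts),
                              counts[unlist(subsets)], 0L)),
    stringsAsFactors = FALSE)
  regions$degree[!grepl("&", regions$region, fixed = TRUE)] <- 1L
  list(regions = regions,
       set_sizes = vapply(sets, length, integer(1)),
       union_size = length(universe))
}
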