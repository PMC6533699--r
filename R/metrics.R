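#' Assembly summary metrics
#'
#' Contig count, maximum and mean contig length, the number of contigs
#' containing an ORF of at least `min_aa` residues, and the mean
#' percentage of an ORF-bearing contig covered by its longest ORF
#' (stop codon included).
#'
#' @param contigs nucleotide [seq_records] (>= 1 contig).
#' @param min_aa longest-ORF cutoff in residues.
#' @return A list of class `assembly_metrics` with `n_contigs`,
#'   `max_len`, `mean_len`, `n_with_orf`, `mean_orf_coverage` (`NA` when
#'   no contig has an ORF).
#' @export
assembly_metrics <- function(contigs, min_aa = 100L) {
  if (is.null(nrow(contigs)) || nrow(contigs) == 0)
    stop("need at least one contig")
  lens <- nchar(contigs$seq)
  cov <- vapply(seq_len(nrow(contigs)), function(i) {
    orf <- longest_orf(contigs[i, , drop = FALSE], min_aa = min_aa)
    if (is.null(orf)) NA_real_
    else 100 * nchar(orf$nuc_seq) / lens[i]
  }, numeric(1))
  structure(list(
    n_contigs = nrow(contigs),
    max_len = max(lens),
    mean_len = mean(lens),
    n_with_orf = sum(!is.na(cov)),
    mean_orf_coverage = if (all(is.na(cov))) NA_real_
                        else mean(cov, na.rm = TRUE)),
    class = "assembly_metrics")
}

#' @export
format.assembly_metrics <- function(x, ...) {
  sprintf(paste0("assembly metrics: %d contigs, max %d nt, mean %.1f nt, ",
                 "%d with ORF, mean ORF coverage %.1f%%"),
          x$n_contigs, x$max_len, x$mean_len, x$n_with_orf,
          x$mean_orf_coverage)
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
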