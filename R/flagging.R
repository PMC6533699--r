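#' Signed identity difference of an orthology record
#'
#' Target identity (percent of the orthologous sequence matching the
#' reference) minus query identity (percent of the reference matching
#' the orthologue). A strongly positive value suggests the orthologue is
#' missing a fragment; a strongly negative one that it is too long.
#'
#' @param target_identity,query_identity percentages in \code{[0, 100]}
#'   (vectorised).
#' @return Signed difference(s).
#' @export
identity_difference <- function(target_identity, query_identity) {
  stopifnot(all(target_identity >= 0 & target_identity <= 100),
            all(query_identity >= 0 & query_identity <= 100))
  target_identity - query_identity
}

#' Per-species outlier threshold: mean + 2 standard deviations
#'
#' Computed on the absolute identity differences by default, with the
#' sample (n - 1) standard deviation.
#'
#' @param diffs signed identity differences (length >= 2).
#' @param absolute compute the statistics on `abs(diffs)` (default) or
#'   on the signed values.
#' @return The threshold value.
#' @export
species_threshold <- function(diffs, absolute = TRUE) {
  if (length(diffs) < 2)
    stop("need at least 2 values to compute a threshold")
  x <- if (absolute) abs(diffs) else diffs
  mean(x) + 2 * stats::sd(x)
}

#' Flag presumably poorly annotated orthologues
#'
#' Per species, a gene is flagged when its absolute identity difference
#' exceeds the species' mean + 2 SD threshold. The cross-species filter
#' then keeps genes that are flagged in exactly one species, among genes
#' with records in every species — a high difference in a single species
#' points at annotation, not evolutionary divergence.
#'
#' @param table data frame with columns `gene_id`, `species`,
#'   `target_identity`, `query_identity`; one row per gene x species.
#' @param absolute see [species_threshold].
#' @param cross_species compute the single-species filter (requires
#'   >= 2 species; default TRUE).
#' @return A list of class `flag_table`: `flags` (per-record data frame
#'   with `diff`, `abs_diff`, `threshold`, `flagged`), `thresholds`
#'   (named per species), `flagged_by_species` (named list of gene ids),
#'   `cross_species` (character vector of gene ids).
#' @export
flag_genes <- function(table, absolute = TRUE, cross_species = TRUE) {
  need <- c("gene_id", "species", "target_identity", "query_identity")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  key <- paste(table$gene_id, table$species, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated gene x species record(s): ",
         paste(unique(table$gene_id[duplicated(key)]), collapse = ", "))
  species <- unique(table$species)
  if (cross_species && length(species) < 2)
    stop("cross-species filter needs records from >= 2 species")
  table$diff <- identity_difference(table$target_identity,
                                    table$query_identity)
  table$abs_diff <- abs(table$diff)
  thresholds <- vapply(species, function(sp) {
    species_threshold(table$diff[table$species == sp], absolute)
  }, numeric(1))
  table$threshold <- thresholds[table$species]
  table$flagged <- table$abs_diff > table$threshold
  flagged_by_species <- lapply(species, function(sp) {
    table$gene_id[table$species == sp & table$flagged]
  })
  names(flagged_by_species) <- species
  cross <- character(0)
  if (cross_species) {
    counts <- base::table(table$gene_id)
    complete <- names(counts)[counts == length(species)]
    n_flag <- vapply(complete, function(g) {
      sum(table$flagged[table$gene_id == g])
    }, numeric(1))
    cross <- complete[n_flag == 1]
  }
  structure(list(flags = table, thresholds = thresholds,
                 flagged_by_species = flagged_by_species,
                 cross_species = cross),
            class = "flag_table")
}

#' Read an orthology identity table
#'
#' Tab- or comma-separated file with header columns `gene_id`,
#' `species`, `target_identity`, `query_identity` (the shape of an
#' orthology-database export).
#'
#' @param path file path (`.csv` read as comma-separated, anything else
#'   as tab-separated).
#' @return A data frame.
#' @export
read_orthology_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE)
  else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "target_identity", "query_identity")
  if (!all(need %in% names(df)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  df
}
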