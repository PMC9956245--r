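#' Homology edge test for one protein pair
#'
#' Applies the family-inclusion rule to the significant HSPs of one
#' unordered protein pair: an edge is emitted iff the HSP-union coverage
#' is at least `coverage_min` on *both* proteins and the
#' alignment-length-weighted mean positive-score similarity fraction is
#' strictly greater than `similarity_min`. Boundaries follow the rule's
#' wording: coverage exactly at the threshold passes ("at least"),
#' similarity exactly at the threshold fails ("over").
#'
#' @param hits HSP data frame for the pair (query = protein a,
#'   subject = protein b), all rows already E-value significant.
#' @param len_a,len_b Protein lengths (residues).
#' @param coverage_min Minimum HSP-union coverage (default 0.80).
#' @param similarity_min Similarity threshold, strict (default 0.50).
#' @return One-row data frame (`locus_a`, `locus_b`, `coverage_a`,
#'   `coverage_b`, `similarity`, `best_evalue`) or `NULL` when the rule
#'   fails.
#' @export
edge_test <- function(hits, len_a, len_b,
                      coverage_min = 0.80, similarity_min = 0.50) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  cov_a <- coverage_fraction(hits, len_a, "query")
  cov_b <- coverage_fraction(hits, len_b, "subject")
  w <- hits$aligned_cols
  sim <- sum(w * hits$similarity_fraction) / sum(w)
  if (cov_a >= coverage_min && cov_b >= coverage_min && sim > similarity_min)
    data.frame(locus_a = hits$query[1L], locus_b = hits$subject[1L],
               coverage_a = cov_a, coverage_b = cov_b, similarity = sim,
               best_evalue = min(hits$evalue), stringsAsFactors = FALSE)
  else NULL
}

#' Homology edges from an all-vs-all hit table
#'
#' Groups HSPs by unordered protein pair (self-hits excluded;
#' within-strain pairs allowed, so paralogs may share a family) and
#' applies [edge_test()] to each.
#'
#' @param hits HSP data frame from [all_vs_all_hits()].
#' @param lengths Named integer vector of protein lengths.
#' @inheritParams edge_test
#' @return Data frame of accepted edges (zero rows when none).
#' @export
homology_edges <- function(hits, lengths,
                           coverage_min = 0.80, similarity_min = 0.50) {
  empty <- data.frame(locus_a = character(0), locus_b = character(0),
                      coverage_a = numeric(0), coverage_b = numeric(0),
                      similarity = numeric(0), best_evalue = numeric(0),
                      stringsAsFactors = FALSE)
  h <- hits[hits$query != hits$subject, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  miss <- setdiff(unique(c(h$query, h$subject)), names(lengths))
  if (length(miss))
    stop("no length known for loci: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(h$query, h$subject, sep = "\r")
  out <- lapply(split(h, key), function(hp)
    edge_test(hp, lengths[[hp$query[1L]]], lengths[[hp$subject[1L]]],
              coverage_min, similarity_min))
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$locus_a, out$locus_b), , drop = FALSE]
}

#' Build protein families as connected components of the homology graph
#'
#' Single-linkage clustering: families are the connected components of
#' the edge graph; loci without any edge form singleton families. Family
#' ids are deterministic (the lexicographically smallest member locus).
#'
#' @param edges Edge data frame from [homology_edges()] (columns
#'   `locus_a`, `locus_b`; extra columns ignored).
#' @param all_loci Either a character vector of locus ids or a data
#'   frame with columns `strain_id` and `locus_id` (as from
#'   [panel_loci()]); the locus universe to partition.
#' @return Data frame `family_id`, `strain_id`, `locus_id` (strain `NA`
#'   when `all_loci` was a bare character vector), sorted by family then
#'   locus.
#' @export
build_families <- function(edges, all_loci) {
  if (is.character(all_loci))
    all_loci <- data.frame(strain_id = NA_character_, locus_id = all_loci,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(all_loci$locus_id))
    stop("duplicate locus ids in the locus universe", call. = FALSE)
  unknown <- setdiff(unique(c(edges$locus_a, edges$locus_b)),
                     all_loci$locus_id)
  if (length(unknown))
    stop("edge endpoints not in the locus universe: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("locus_a", "locus_b"), drop = FALSE],
    directed = FALSE, vertices = all_loci$locus_id)
  comp <- igraph::components(g)$membership
  fam_of_comp <- tapply(names(comp), comp, function(v) min(v))
  fam <- unname(fam_of_comp[as.character(comp[all_loci$locus_id])])
  out <- data.frame(family_id = fam, strain_id = all_loci$strain_id,
                    locus_id = all_loci$locus_id, stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Family-by-strain presence/count matrix
#'
#' @param families Data frame with `family_id`, `strain_id`, `locus_id`.
#' @param strain_metadata Metadata data frame covering every member
#'   strain (see [strain_panel()]); its strain order defines the column
#'   order, so strains with no family member appear as all-zero columns.
#' @return Integer matrix (families x strains) of member counts, with
#'   the metadata attached as attribute `"metadata"`.
#' @export
presence_matrix <- function(families, strain_metadata) {
  miss <- setdiff(unique(families$strain_id), strain_metadata$strain_id)
  if (length(miss))
    stop("strains missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  fam_ids <- sort(unique(families$family_id))
  m <- matrix(0L, nrow = length(fam_ids),
              ncol = nrow(strain_metadata),
              dimnames = list(fam_ids, strain_metadata$strain_id))
  if (nrow(families)) {
    tab <- table(families$family_id, families$strain_id)
    m[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  attr(m, "metadata") <- strain_metadata
  m
}
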