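#' Detect within-genome paralogs of one protein
#'
#' Reports the other loci of the same proteome whose *best* local
#' alignment to the query covers strictly more than `coverage_min` of
#' the full query length with an identity fraction strictly greater
#' than `identity_min` (defaults: coverage > 50%, identity > 30%; both
#' inequalities strict, so values exactly at a threshold are rejected).
#'
#' @param locus Locus id of the query; must be present in `proteome`.
#' @param proteome Named character vector of one strain's proteins.
#' @param matrix,params Scoring scheme as in [local_align()].
#' @param coverage_min Query-length coverage threshold (strict).
#' @param identity_min Identity-fraction threshold (strict).
#' @return Character vector of paralog locus ids (possibly empty),
#'   sorted.
#' @export
detect_paralogs <- function(locus, proteome, matrix = blosum62(),
                            params = alignment_params(),
                            coverage_min = 0.5, identity_min = 0.3) {
  if (!locus %in% names(proteome))
    stop("locus ", locus, " is not in the proteome", call. = FALSE)
  query <- proteome[[locus]]
  qlen <- nchar(query)
  others <- setdiff(names(proteome), locus)
  hits <- vapply(others, function(o) {
    h <- local_align(query, proteome[[o]], matrix, params,
                     id_a = locus, id_b = o)
    if (nrow(h) == 0L) return(FALSE)
    top <- h[which.max(h$score), ]
    cov <- (top$q_end - top$q_start + 1L) / qlen
    cov > coverage_min && top$identity_fraction > identity_min
  }, logical(1))
  sort(others[hits])
}

#' Within-strain paralog pairs from an all-vs-all hit table
#'
#' Hit-table counterpart of [detect_paralogs()] used by the pipeline:
#' for every ordered within-strain pair (query, subject), the top HSP is
#' tested against the strict coverage/identity rule on the query length.
#'
#' @param hits HSP data frame from [all_vs_all_hits()] (contains each
#'   unordered pair once; both orientations are derived internally,
#'   spans swapped for the reverse direction).
#' @param lengths Named protein lengths.
#' @param strains Named character vector locus -> strain id.
#' @inheritParams detect_paralogs
#' @return Data frame `strain_id`, `locus`, `paralog` (one row per
#'   directed call).
#' @export
paralog_pairs_from_hits <- function(hits, lengths, strains,
                                    coverage_min = 0.5, identity_min = 0.3) {
  h <- hits[hits$query != hits$subject &
              strains[hits$query] == strains[hits$subject], , drop = FALSE]
  empty <- data.frame(strain_id = character(0), locus = character(0),
                      paralog = character(0), stringsAsFactors = FALSE)
  if (nrow(h) == 0L) return(empty)
  rev <- h
  rev$query <- h$subject; rev$subject <- h$query
  rev$q_start <- h$s_start; rev$q_end <- h$s_end
  rev$s_start <- h$q_start; rev$s_end <- h$q_end
  both <- rbind(h, rev)
  key <- paste(both$query, both$subject, sep = "\r")
  top <- both[order(key, -both$score), ]
  top <- top[!duplicated(paste(top$query, top$subject, sep = "\r")), ]
  cov <- (top$q_end - top$q_start + 1L) / lengths[top$query]
  keep <- cov > coverage_min & top$identity_fraction > identity_min
  out <- data.frame(strain_id = unname(strains[top$query[keep]]),
                    locus = top$query[keep], paralog = top$subject[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$strain_id, out$locus, out$paralog), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify lost families by copy-number redundancy
#'
#' A lost family is `several_copies` iff at least one of its members in
#' a retained-group genome has at least one detected paralog, and
#' `single_copy` otherwise. Every member of every lost family must have
#' a paralog-call entry (queried members take the union of calls).
#'
#' @param lost_family_ids Family ids to classify.
#' @param families Family membership data frame (`family_id`,
#'   `strain_id`, `locus_id`).
#' @param paralog_calls Named list locus -> character vector of detected
#'   paralog loci (may be empty vectors, not missing).
#' @param retained_strains Strain ids of the retained group; only
#'   members in these genomes count.
#' @return Named character vector family id ->
#'   `"several_copies"`/`"single_copy"`.
#' @export
classify_copy_number <- function(lost_family_ids, families, paralog_calls,
                                 retained_strains) {
  out <- setNames(character(length(lost_family_ids)), lost_family_ids)
  for (f in lost_family_ids) {
    members <- families[families$family_id == f &
                          families$strain_id %in% retained_strains, ]
    miss <- setdiff(members$locus_id, names(paralog_calls))
    if (length(miss))
      stop("paralog calls missing for loci: ",
           paste(miss, collapse = ", "), call. = FALSE)
    n_para <- vapply(paralog_calls[members$locus_id], length, 1L)
    out[[f]] <- if (any(n_para > 0L)) "several_copies" else "single_copy"
  }
  out
}

#' Read a lost-family annotation table
#'
#' TSV with columns `copy_class`, `cog`, `locus`, `gene`, `product`,
#' `paralogs` (comma-separated locus list, possibly empty) and
#' `localization` (`SP`, `TM` or empty). COG labels are single COG
#' category letters or `NI` (not in COGs).
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_annotation_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("cog", "locus", "gene", "product", "paralogs", "localization")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$locus))
    stop("duplicate locus in annotation table: ",
         x$locus[duplicated(x$locus)][1L], call. = FALSE)
  if (!all(x$localization %in% c("SP", "TM", "")))
    stop("localization must be SP, TM or empty", call. = FALSE)
  x
}

#' Packaged lost-family annotation table
#'
#' The 88 protein families found in all six non-sporulating (Sp-)
#' *Alnus*-infective *Frankia* genomes and absent from all six
#' sporulating (Sp+) genomes, as published, with their COG category,
#' reference-genome accession, product, listed paralogs and predicted
#' localization (SP = secreted, TM = transmembrane).
#'
#' @return Data frame of 88 annotation records.
#' @export
lost_family_annotations <- function() {
  read_annotation_table(system.file("extdata", "spminus_lost_families.tsv",
                                    package = "frankiapan", mustWork = TRUE))
}

#' Summarize lost families by COG, localization and paralogy
#'
#' Counts records per COG category (percentages to one decimal),
#' records localized as secreted or transmembrane and records with at
#' least one listed paralog (both as counts and whole-number
#' percentages).
#'
#' @param records Annotation data frame (see [read_annotation_table()]).
#' @return An object of class `lost_family_summary`: list with `total`,
#'   `cog_counts`, `cog_percents`, `tm_or_sp` (`count`, `percent`) and
#'   `with_paralogs` (`count`, `percent`).
#' @export
summarize_lost_families <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no annotation records supplied", call. = FALSE)
  total <- nrow(records)
  cog_counts <- table(factor(records$cog))
  cog_counts <- cog_counts[order(names(cog_counts))]
  tm_sp <- sum(records$localization %in% c("SP", "TM"))
  with_para <- sum(nzchar(trimws(records$paralogs)))
  structure(list(
    total = total,
    cog_counts = cog_counts,
    cog_percents = round(100 * as.numeric(cog_counts) / total, 1) |>
      setNames(names(cog_counts)),
    tm_or_sp = list(count = tm_sp, percent = round(100 * tm_sp / total)),
    with_paralogs = list(count = with_para,
                         percent = round(100 * with_para / total))),
    class = "lost_family_summary")
}

#' @export
print.lost_family_summary <- function(x, ...) {
  cat("Lost-family summary:", x$total, "families\n")
  cat("  by COG category:\n")
  for (i in seq_along(x$cog_counts))
    cat(sprintf("    %-2s %3d  (%.1f%%)\n", names(x$cog_counts)[i],
                x$cog_counts[i], x$cog_percents[i]))
  cat(sprintf("  secreted or transmembrane: %d (%d%%)\n",
              x$tm_or_sp$count, x$tm_or_sp$percent))
  cat(sprintf("  with listed paralogs:      %d (%d%%)\n",
              x$with_paralogs$count, x$with_paralogs$percent))
  invisible(x)
}
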