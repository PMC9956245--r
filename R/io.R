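#' Strain panel container
#'
#' A validated bundle of per-strain proteomes and strain metadata.
#'
#' @param proteomes Named list (by strain id) of named character vectors
#'   (locus id -> protein sequence). Locus ids must be unique within a
#'   strain and across the panel.
#' @param metadata Data frame with columns `strain_id`, `cluster_label`,
#'   `phenotype`; every proteome strain must appear exactly once.
#' @return An object of class `strain_panel`.
#' @export
strain_panel <- function(proteomes, metadata) {
  if (!is.list(proteomes) ||
      (length(proteomes) && is.null(names(proteomes))))
    stop("proteomes must be a named list of named character vectors",
         call. = FALSE)
  need <- c("strain_id", "cluster_label", "phenotype")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata)))
    stop("metadata needs columns strain_id, cluster_label, phenotype",
         call. = FALSE)
  if (anyDuplicated(metadata$strain_id))
    stop("duplicate strain_id in metadata", call. = FALSE)
  unknown <- setdiff(names(proteomes), metadata$strain_id)
  if (length(unknown))
    stop("strains absent from metadata: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  all_loci <- unlist(lapply(proteomes, names), use.names = FALSE)
  dup <- all_loci[duplicated(all_loci)]
  if (length(dup))
    stop("duplicate locus ids across the panel: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  for (s in names(proteomes)) {
    p <- proteomes[[s]]
    if (length(p) && (is.null(names(p)) || any(!nzchar(names(p)))))
      stop("proteome of strain ", s, " has unnamed sequences", call. = FALSE)
    proteomes[[s]] <- toupper(p)
  }
  metadata <- metadata[, need, drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(proteomes = proteomes, metadata = metadata),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  n <- vapply(x$proteomes, length, 1L)
  cat("strain_panel:", length(x$proteomes), "strains,",
      sum(n), "proteins\n")
  md <- x$metadata
  md$n_proteins <- n[md$strain_id]
  print(md, row.names = FALSE)
  invisible(x)
}

#' Flatten a panel to a named sequence vector
#'
#' @param panel A [strain_panel()].
#' @return Named character vector of all protein sequences (names are
#'   locus ids, unique across the panel).
#' @export
panel_seqs <- function(panel) {
  out <- unlist(unname(panel$proteomes))
  if (is.null(out)) out <- setNames(character(0), character(0))
  out
}

#' Locus table of a panel
#'
#' @param panel A [strain_panel()].
#' @return Data frame with `strain_id`, `locus_id`, `length`.
#' @export
panel_loci <- function(panel) {
  rows <- lapply(names(panel$proteomes), function(s) {
    p <- panel$proteomes[[s]]
    if (!length(p)) return(NULL)
    data.frame(strain_id = s, locus_id = names(p), length = nchar(p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(strain_id = character(0), locus_id = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  out
}

#' Read per-strain protein FASTA files into a panel
#'
#' FASTA headers must be `strain|locus`; each file may carry one or more
#' strains, all of which must be listed in the metadata table.
#'
#' @param paths Character vector of protein FASTA paths.
#' @param metadata Strain metadata data frame (see [strain_panel()]) or
#'   a path to a TSV with the same columns.
#' @return A [strain_panel()].
#' @export
read_proteomes <- function(paths, metadata) {
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  proteomes <- list()
  for (path in paths) {
    x <- Biostrings::readAAStringSet(path)
    if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
    hdr <- sub("\\s.*$", "", names(x))
    parts <- strsplit(hdr, "|", fixed = TRUE)
    if (any(vapply(parts, length, 1L) != 2L))
      stop("header not of the form strain|locus in ", path, call. = FALSE)
    strain <- vapply(parts, `[`, character(1), 1L)
    locus <- vapply(parts, `[`, character(1), 2L)
    if (anyDuplicated(hdr))
      stop("duplicate FASTA header '", hdr[duplicated(hdr)][1L],
           "' in ", path, call. = FALSE)
    seqs <- toupper(as.character(x))
    for (s in unique(strain)) {
      add <- setNames(seqs[strain == s], locus[strain == s])
      if (any(names(add) %in% names(proteomes[[s]])))
        stop("duplicate locus for strain ", s, " in ", path, call. = FALSE)
      proteomes[[s]] <- c(proteomes[[s]], add)
    }
  }
  unknown <- setdiff(names(proteomes), metadata$strain_id)
  if (length(unknown))
    stop("strains not in metadata: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  strain_panel(proteomes, metadata)
}

#' G+C content of nucleotide sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` and other ambiguity letters are
#' excluded from the denominator. `NaN` for sequences with no
#' unambiguous base.
#'
#' @param seqs Character vector (or `DNAStringSet`) of sequences.
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  counts <- function(ch) vapply(seqs, function(s)
    sum(charToRaw(s) == charToRaw(ch)), 1L, USE.NAMES = FALSE)
  gc <- counts("G") + counts("C")
  acgt <- gc + counts("A") + counts("T")
  ifelse(acgt == 0, NaN, gc / acgt)
}

#' GC-content read contamination filter
#'
#' Removes reads whose G+C fraction is less than or equal to `max_gc`
#' (boundary removed): in a high-GC bacterial sequencing project,
#' low-GC reads are treated as host-plant contamination. Empty reads and
#' reads with no unambiguous base are removed with a warning.
#'
#' @param reads Named character vector (or `DNAStringSet`) of reads.
#' @param max_gc Removal threshold on the GC fraction (default 0.54).
#' @return `list(kept =, removed =)` of named character vectors.
#' @examples
#' gc_read_filter(c(r1 = "GCGCGCGCGC", r2 = "ATATATGCGC"))
#' @export
gc_read_filter <- function(reads, max_gc = 0.54) {
  reads <- setNames(toupper(as.character(reads)), names(reads))
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  gc <- gc_content(reads)
  invalid <- is.nan(gc)
  if (any(invalid))
    warning(sum(invalid), " read(s) with no unambiguous base removed")
  drop <- invalid | (!invalid & gc <= max_gc)
  list(kept = reads[!drop], removed = reads[drop])
}

#' Read a nucleotide FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
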