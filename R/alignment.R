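#' Alignment parameters
#'
#' Bundles the affine gap penalties, Karlin-Altschul constants and the
#' E-value significance threshold used throughout the alignment layer.
#' A gap of length L costs `gap_open + gap_extend * L`. The defaults pair
#' BLOSUM62 with open 11 / extend 1 and the published gapped-BLOSUM62
#' Karlin-Altschul constants (lambda = 0.267, K = 0.041); the E-value
#' cutoff of 1e-4 is the homology-search significance threshold.
#'
#' @param gap_open Positive gap-opening penalty.
#' @param gap_extend Positive per-residue gap-extension penalty.
#' @param karlin_lambda Karlin-Altschul lambda (per score unit).
#' @param karlin_K Karlin-Altschul K.
#' @param evalue_threshold Maximum E-value for a reported HSP.
#' @param max_hsps Maximum HSPs returned per sequence pair (the optimal
#'   alignment plus greedily masked, non-overlapping suboptimals).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(gap_open = 11, gap_extend = 1,
                             karlin_lambda = 0.267, karlin_K = 0.041,
                             evalue_threshold = 1e-4, max_hsps = 10L) {
  if (gap_open <= 0) stop("gap_open must be > 0", call. = FALSE)
  if (gap_extend <= 0) stop("gap_extend must be > 0", call. = FALSE)
  if (karlin_lambda <= 0) stop("karlin_lambda must be > 0", call. = FALSE)
  if (karlin_K <= 0) stop("karlin_K must be > 0", call. = FALSE)
  if (evalue_threshold <= 0) stop("evalue_threshold must be > 0", call. = FALSE)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_K = karlin_K,
                 evalue_threshold = evalue_threshold,
                 max_hsps = as.integer(max_hsps)),
            class = "alignment_params")
}

# Error if a sequence contains letters outside the matrix alphabet; the
# message names the offending locus and 1-based position.
check_residues <- function(seq, alphabet, locus = "sequence") {
  if (!nzchar(seq)) stop("empty sequence for ", locus, call. = FALSE)
  bad <- regexpr(sprintf("[^%s]", alphabet), seq)
  if (bad > 0L)
    stop("residue '", substr(seq, bad, bad), "' at position ", bad,
         " of ", locus, " is outside the scoring alphabet", call. = FALSE)
  invisible(TRUE)
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments with at least the given raw
#' score between two random sequences of lengths `m` and `n`:
#' `K * m * n * exp(-lambda * score)`.
#'
#' @param score Raw alignment score.
#' @param query_len,subject_len Sequence lengths (residues, > 0).
#' @param params An [alignment_params()] object supplying lambda and K.
#' @return Numeric E-value (vectorised over `score`).
#' @export
karlin_evalue <- function(score, query_len, subject_len,
                          params = alignment_params()) {
  if (any(query_len <= 0) || any(subject_len <= 0))
    stop("sequence lengths must be > 0", call. = FALSE)
  params$karlin_K * query_len * subject_len *
    exp(-params$karlin_lambda * score)
}

#' Local protein alignment (Smith-Waterman, affine gaps)
#'
#' Exact affine-gap Smith-Waterman between two protein sequences. The
#' optimal HSP is reported first; residues on its path are then masked on
#' both sequences and the dynamic programme is re-run, yielding
#' non-overlapping suboptimal HSPs until the best remaining alignment
#' exceeds the E-value threshold. Identity and similarity fractions are
#' computed over gap-free aligned columns only; a residue pair is similar
#' when its substitution score is positive, so
#' `identity_fraction <= similarity_fraction` always holds.
#'
#' @param a,b Protein sequences (character scalars; names, if present,
#'   are used as locus ids).
#' @param matrix Substitution matrix, default [blosum62()].
#' @param params [alignment_params()].
#' @param id_a,id_b Locus ids for reporting.
#' @return A data frame of HSPs sorted by ascending E-value with columns
#'   `query`, `subject`, `score`, `evalue`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (1-based inclusive), `aligned_cols`, `align_length`,
#'   `mismatches`, `gap_opens`, `gap_residues`, `identity_fraction`,
#'   `similarity_fraction`. Zero rows when no HSP passes the threshold.
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")
#' @export
local_align <- function(a, b, matrix = blosum62(),
                        params = alignment_params(),
                        id_a = if (!is.null(names(a))) names(a) else "query",
                        id_b = if (!is.null(names(b))) names(b) else "subject") {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  alphabet <- paste(rownames(matrix), collapse = "")
  check_residues(a, alphabet, id_a)
  check_residues(b, alphabet, id_b)
  h <- cpp_local_align(a, b, matrix, alphabet,
                       params$gap_open, params$gap_extend,
                       params$karlin_lambda, params$karlin_K,
                       params$evalue_threshold, params$max_hsps)
  finish_hits(h, id_a, id_b)
}

finish_hits <- function(h, query_ids, subject_ids) {
  h$query <- query_ids[h$query_idx]
  h$subject <- subject_ids[h$subject_idx]
  h$query_idx <- NULL
  h$subject_idx <- NULL
  front <- c("query", "subject")
  h <- h[c(front, setdiff(names(h), front))]
  h <- h[order(h$evalue, -h$score, h$query, h$subject), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' All-vs-all local alignment over a strain panel
#'
#' Runs the exact local aligner on every unordered pair of proteins in a
#' panel (self-pairs included, so self-hit dominance can be checked).
#' With `prefilter = TRUE` (default), pairs of distinct proteins that
#' share no exact k-mer word (k = `prefilter_k`, standard residues only)
#' are skipped before dynamic programming; at the divergences relevant to
#' family building such pairs cannot yield a significant HSP, while
#' unrelated random sequences are overwhelmingly excluded.
#'
#' @param panel A [strain_panel()] (or a named character vector of
#'   sequences, in which case strain bookkeeping is skipped).
#' @param matrix,params Scoring scheme, as in [local_align()].
#' @param prefilter Logical; apply the shared k-mer pair prefilter.
#' @param prefilter_k Word length for the prefilter.
#' @return HSP data frame as in [local_align()], with `query`/`subject`
#'   giving locus ids.
#' @export
all_vs_all_hits <- function(panel, matrix = blosum62(),
                            params = alignment_params(),
                            prefilter = TRUE, prefilter_k = 5L) {
  seqs <- if (inherits(panel, "strain_panel")) panel_seqs(panel) else panel
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique locus names", call. = FALSE)
  alphabet <- paste(rownames(matrix), collapse = "")
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) check_residues(seqs[[i]], alphabet, names(seqs)[i])
  h <- cpp_all_vs_all(unname(seqs), matrix, alphabet,
                      params$gap_open, params$gap_extend,
                      params$karlin_lambda, params$karlin_K,
                      params$evalue_threshold, params$max_hsps,
                      TRUE, prefilter, as.integer(prefilter_k))
  finish_hits(h, names(seqs), names(seqs))
}

#' HSP-union coverage of a protein
#'
#' Fraction of a protein covered by the union of HSP intervals on the
#' chosen side; overlapping HSPs are counted once.
#'
#' @param hits HSP data frame (as returned by [local_align()]).
#' @param protein_len Protein length in residues.
#' @param side `"query"` or `"subject"`.
#' @return Covered fraction in \[0, 1\]; 0 for an empty hit list.
#' @export
coverage_fraction <- function(hits, protein_len, side = c("query", "subject")) {
  side <- match.arg(side)
  if (is.null(hits) || nrow(hits) == 0L) return(0)
  st <- hits[[if (side == "query") "q_start" else "s_start"]]
  en <- hits[[if (side == "query") "q_end" else "s_end"]]
  if (any(st < 1L) || any(en > protein_len) || any(en < st))
    stop("HSP span outside [1, ", protein_len, "]", call. = FALSE)
  covered <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(st, en))))
  covered / protein_len
}

#' Global percent identity (Needleman-Wunsch, affine gaps)
#'
#' Aligns two sequences end to end under the same substitution matrix and
#' gap penalties as the local aligner and reports
#' `100 * identities / aligned residue-residue columns`, rounded to two
#' decimals. With `gap_inclusive = TRUE` the denominator is the full
#' alignment length including gap columns.
#'
#' @inheritParams local_align
#' @param gap_inclusive Logical; include gap columns in the denominator.
#' @return Percent identity (scalar, two decimals).
#' @examples
#' global_percent_identity("ACDE", "ACDF")  # 75
#' @export
global_percent_identity <- function(a, b, matrix = blosum62(),
                                    params = alignment_params(),
                                    gap_inclusive = FALSE) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  alphabet <- paste(rownames(matrix), collapse = "")
  check_residues(a, alphabet, "first sequence")
  check_residues(b, alphabet, "second sequence")
  r <- cpp_global_identity(a, b, matrix, alphabet,
                           params$gap_open, params$gap_extend)
  denom <- if (gap_inclusive) r[["align_length"]] else r[["aligned_cols"]]
  if (denom == 0) return(0)
  round(100 * r[["identities"]] / denom, 2)
}

#' Write HSPs as a 12-column BLAST-style tabular file
#'
#' Columns: query, subject, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, E-value,
#' score (coordinates 1-based inclusive).
#'
#' @param hits HSP data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(
    query = hits$query, subject = hits$subject,
    pident = sprintf("%.2f", 100 * hits$identity_fraction),
    length = hits$align_length, mismatch = hits$mismatches,
    gapopen = hits$gap_opens,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$s_start, send = hits$s_end,
    evalue = format(hits$evalue, digits = 3, scientific = TRUE),
    bitscore = hits$score,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
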