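#' BLOSUM62 substitution matrix
#'
#' Returns the standard BLOSUM62 amino-acid substitution matrix (integer
#' scores, symmetric) over the 20 standard residues plus the ambiguity
#' codes B, J, Z and X. Two residues are considered *similar* when their
#' entry is positive; every diagonal entry for a standard residue is
#' positive, so identity implies similarity.
#'
#' @return An integer matrix with identical row and column names giving
#'   the scoring alphabet.
#' @examples
#' m <- blosum62()
#' m["W", "W"]  # 11, the largest diagonal score
#' @export
blosum62 <- function() {
  if (is.null(.fp_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    keep <- setdiff(rownames(m), "*")
    m <- m[keep, keep, drop = FALSE]
    storage.mode(m) <- "integer"
    .fp_cache$blosum62 <- validate_substitution_matrix(m, "BLOSUM62")
  }
  .fp_cache$blosum62
}

.fp_cache <- new.env(parent = emptyenv())

validate_substitution_matrix <- function(m, name = "substitution matrix") {
  if (!is.matrix(m) || !identical(rownames(m), colnames(m)))
    stop(name, ": matrix must be square with identical row/column names",
         call. = FALSE)
  std <- strsplit(AA_STANDARD, "")[[1]]
  missing <- setdiff(std, rownames(m))
  if (length(missing))
    stop(name, ": standard residues missing from alphabet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!isTRUE(all(m == t(m))))
    stop(name, ": matrix must be symmetric", call. = FALSE)
  attr(m, "matrix_name") <- name
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI BLAST (`#` comment
#' lines, a header row of single-letter codes, then one labelled row of
#' integer scores per residue).
#'
#' @param path Path to the matrix file.
#' @param name Label attached to the returned matrix.
#' @return Integer score matrix, validated for symmetry and alphabet
#'   completeness.
#' @seealso [write_substitution_matrix()] for the inverse operation.
#' @export
read_substitution_matrix <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("substitution matrix file has no data rows: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1L)
  scores <- lapply(rows, function(r) as.integer(r[-1L]))
  if (any(vapply(scores, length, 1L) != length(header)))
    stop("matrix row lengths do not match the header: ", path, call. = FALSE)
  m <- do.call(rbind, scores)
  dimnames(m) <- list(labels, header)
  m <- m[, labels, drop = FALSE]  # enforce row order on columns
  keep <- setdiff(labels, "*")
  validate_substitution_matrix(m[keep, keep, drop = FALSE], name)
}

#' Write a substitution matrix in NCBI text format
#'
#' @param m Score matrix (square, named).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(m, path) {
  stopifnot(is.matrix(m), identical(rownames(m), colnames(m)))
  header <- paste(c(" ", rownames(m)), collapse = "  ")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%2d", m[i, ])), collapse = " ")
  }, character(1))
  writeLines(c("# substitution matrix", header, body), path)
  invisible(path)
}
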