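#' Pairwise percent-identity matrix of a protein set
#'
#' Global (end-to-end) pairwise alignment of every sequence pair under
#' [global_percent_identity()]; the result is symmetric by construction
#' with a 100.00 diagonal, values to two decimals.
#'
#' @param records Named character vector of protein sequences (>= 2,
#'   unique ids).
#' @param matrix,params Scoring scheme as in [local_align()].
#' @param gap_inclusive Passed to [global_percent_identity()].
#' @return Numeric matrix (ids x ids) of percent identities.
#' @export
build_identity_matrix <- function(records, matrix = blosum62(),
                                  params = alignment_params(),
                                  gap_inclusive = FALSE) {
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids))
    stop("records must carry unique ids", call. = FALSE)
  if (length(records) < 2L)
    stop("need at least two records", call. = FALSE)
  n <- length(records)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- global_percent_identity(records[[i]], records[[j]], matrix, params,
                                 gap_inclusive)
    m[i, j] <- m[j, i] <- v
  }
  m
}

#' Summary statistics of a percent-identity matrix
#'
#' Statistics over the n(n-1)/2 distinct off-diagonal entries; the mean
#' is reported to two decimals, and the extreme pairs are named.
#'
#' @param m Symmetric percent-identity matrix with >= 2 ids.
#' @return List with `n_pairs`, `mean_offdiag`, `min_offdiag`,
#'   `max_offdiag`, `argmin` and `argmax` (character pairs).
#' @export
matrix_summary <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("m must be a square matrix", call. = FALSE)
  if (nrow(m) < 2L)
    stop("need at least a 2 x 2 matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop("m must be symmetric", call. = FALSE)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  v <- m[upper.tri(m)]
  imin <- which.min(v); imax <- which.max(v)
  list(n_pairs = length(v),
       mean_offdiag = round(mean(v), 2),
       min_offdiag = v[imin],
       max_offdiag = v[imax],
       argmin = c(rownames(m)[idx[imin, 1]], colnames(m)[idx[imin, 2]]),
       argmax = c(rownames(m)[idx[imax, 1]], colnames(m)[idx[imax, 2]]))
}

#' Packaged agmatine-deiminase percent-identity matrix
#'
#' The published pairwise percent-identity matrix of the agmatine
#' deiminase (AgD) protein across the 12 *Alnus*-infective *Frankia*
#' strains of Cluster Ia — the group-specific core gene whose
#' conservation the identity-matrix machinery quantifies.
#'
#' @return Symmetric 12 x 12 numeric matrix with a 100 diagonal.
#' @export
agd_identity_matrix <- function() {
  read_identity_tsv(system.file("extdata", "agd_identity_matrix.tsv",
                                package = "frankiapan", mustWork = TRUE))
}

#' Read / write percent-identity matrices as TSV
#'
#' The TSV carries ids as the header row and first column.
#'
#' @param path File path.
#' @return `read_identity_tsv()`: numeric matrix. `write_identity_tsv()`:
#'   `path`, invisibly.
#' @export
read_identity_tsv <- function(path) {
  x <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(x)
  if (!identical(rownames(m), colnames(m)))
    stop("identity matrix ids differ between rows and columns", call. = FALSE)
  m
}

#' @rdname read_identity_tsv
#' @param m Matrix to write.
#' @export
write_identity_tsv <- function(m, path) {
  utils::write.table(cbind(id = rownames(m), format(m, nsmall = 2)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
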