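#' ANI parameters
#'
#' Fragment-based average nucleotide identity settings: genomes are cut
#' into consecutive non-overlapping fragments (default 1020 bp), each
#' fragment is locally aligned to the other genome, and fragments are
#' retained when the best hit reaches at least `min_identity` percent
#' identity over at least `min_coverage` of the fragment length — the
#' standard fragment-ANI (BLAST-ANI) definition. Nucleotide alignment
#' uses match +2 / mismatch -3 with affine gaps open 5 / extend 2;
#' candidate target regions are located by exact `seed_kmer`-mers before
#' the full dynamic programme is run in a window.
#'
#' @param fragment_len Fragment length in bp.
#' @param min_identity Retention threshold, percent identity.
#' @param min_coverage Retention threshold, fragment coverage fraction.
#' @param match,mismatch,gap_open,gap_extend Nucleotide scoring.
#' @param seed_kmer Exact-word length for locating candidate diagonals.
#' @param max_diagonals Candidate windows aligned per fragment.
#' @param window_margin Extra bp on each side of the seeded window.
#' @return List of class `ani_params`.
#' @export
ani_params <- function(fragment_len = 1020L, min_identity = 30,
                       min_coverage = 0.7, match = 2, mismatch = -3,
                       gap_open = 5, gap_extend = 2, seed_kmer = 13L,
                       max_diagonals = 5L, window_margin = 200L) {
  stopifnot(fragment_len > 0, min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 1, gap_open > 0,
            gap_extend > 0, seed_kmer > 3)
  structure(list(fragment_len = as.integer(fragment_len),
                 min_identity = min_identity, min_coverage = min_coverage,
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, seed_kmer = as.integer(seed_kmer),
                 max_diagonals = as.integer(max_diagonals),
                 window_margin = as.integer(window_margin)),
            class = "ani_params")
}

#' Cut a genome into consecutive ANI fragments
#'
#' Non-overlapping windows of `fragment_len` bp; a trailing remainder
#' shorter than `fragment_len` is discarded.
#'
#' @param seq Nucleotide string (length >= `fragment_len`).
#' @param fragment_len Window size in bp (default 1020).
#' @return Character vector of fragments.
#' @export
fragment_genome <- function(seq, fragment_len = 1020L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n < fragment_len)
    stop("sequence (", n, " bp) shorter than one fragment (",
         fragment_len, " bp)", call. = FALSE)
  k <- n %/% fragment_len
  starts <- (seq_len(k) - 1L) * fragment_len + 1L
  substring(seq, starts, starts + fragment_len - 1L)
}

ani_one_direction <- function(source, target, params) {
  frags <- fragment_genome(source, params$fragment_len)
  m <- cpp_map_fragments(frags, toupper(as.character(target)),
                         params$seed_kmer, params$match, params$mismatch,
                         params$gap_open, params$gap_extend,
                         params$max_diagonals, params$window_margin)
  keep <- m[, "identity_pct"] >= params$min_identity &
    m[, "coverage"] >= params$min_coverage
  list(ani = if (any(keep)) mean(m[keep, "identity_pct"]) else NA_real_,
       n_used = sum(keep), n_fragments = length(frags))
}

#' Fragment-based average nucleotide identity of a genome pair
#'
#' Per direction, each fragment of the source genome is aligned to the
#' full target genome and the ANI is the mean percent identity of the
#' retained fragments. Directions are reported separately; a direction
#' with no retained fragment is undefined (`NA`).
#'
#' @param genome_a,genome_b Nucleotide strings.
#' @param params [ani_params()].
#' @param id_a,id_b Genome labels.
#' @return List of class `ani_result` with `genome_a`, `genome_b`,
#'   `ani_ab`, `ani_ba` (percent, `NA` when undefined) and
#'   `n_fragments_used` (named vector, `ab`/`ba`).
#' @export
ani_pair <- function(genome_a, genome_b, params = ani_params(),
                     id_a = "genome_a", id_b = "genome_b") {
  ab <- ani_one_direction(genome_a, genome_b, params)
  ba <- ani_one_direction(genome_b, genome_a, params)
  structure(list(genome_a = id_a, genome_b = id_b,
                 ani_ab = ab$ani, ani_ba = ba$ani,
                 n_fragments_used = c(ab = ab$n_used, ba = ba$n_used)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("ANI %s -> %s: %s (%d fragments)\n", x$genome_a, x$genome_b,
              fmt(x$ani_ab), x$n_fragments_used[["ab"]]))
  cat(sprintf("ANI %s -> %s: %s (%d fragments)\n", x$genome_b, x$genome_a,
              fmt(x$ani_ba), x$n_fragments_used[["ba"]]))
  invisible(x)
}

#' Pairwise ANI over a set of genomes
#'
#' @param genomes Named character vector (or list) of nucleotide
#'   strings.
#' @param params [ani_params()].
#' @return Data frame with one row per unordered pair: `genome_a`,
#'   `genome_b`, `ani_ab`, `ani_ba`, `n_used_ab`, `n_used_ba`.
#' @export
ani_matrix <- function(genomes, params = ani_params()) {
  ids <- names(genomes)
  if (is.null(ids) || anyDuplicated(ids))
    stop("genomes must carry unique names", call. = FALSE)
  rows <- list()
  for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
    if (j <= i) next
    r <- ani_pair(genomes[[i]], genomes[[j]], params, ids[i], ids[j])
    rows[[length(rows) + 1L]] <- data.frame(
      genome_a = r$genome_a, genome_b = r$genome_b,
      ani_ab = r$ani_ab, ani_ba = r$ani_ba,
      n_used_ab = r$n_fragments_used[["ab"]],
      n_used_ba = r$n_fragments_used[["ba"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species delineation from ANI results
#'
#' Builds a graph with an edge between two genomes when the mean of the
#' two directional ANI values reaches the threshold (default 95%, the
#' conventional bacterial species boundary) and returns the connected
#' components as species, labelled by their lexicographically smallest
#' member.
#'
#' @param results Data frame as from [ani_matrix()] (or a list of
#'   [ani_pair()] results); each unordered pair at most once.
#' @param threshold Percent ANI species threshold.
#' @return Named character vector genome id -> species label.
#' @export
species_components <- function(results, threshold = 95) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(genome_a = r$genome_a, genome_b = r$genome_b,
                 ani_ab = r$ani_ab, ani_ba = r$ani_ba,
                 stringsAsFactors = FALSE)))
  key <- apply(cbind(results$genome_a, results$genome_b), 1L,
               function(p) paste(sort(p), collapse = "\r"))
  if (anyDuplicated(key))
    stop("duplicate genome pair in ANI results", call. = FALSE)
  ids <- sort(unique(c(results$genome_a, results$genome_b)))
  mean_ani <- rowMeans(cbind(results$ani_ab, results$ani_ba))
  keep <- !is.na(mean_ani) & mean_ani >= threshold
  g <- igraph::graph_from_data_frame(
    results[keep, c("genome_a", "genome_b"), drop = FALSE],
    directed = FALSE, vertices = ids)
  comp <- igraph::components(g)$membership
  labels <- tapply(names(comp), comp, min)
  setNames(unname(labels[as.character(comp[ids])]), ids)
}

#' Write an asymmetric ANI matrix as TSV
#'
#' Rows are source genomes, columns target genomes, diagonal 100.
#'
#' @param results [ani_matrix()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ani_tsv <- function(results, path) {
  ids <- sort(unique(c(results$genome_a, results$genome_b)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_len(nrow(results))) {
    m[results$genome_a[i], results$genome_b[i]] <- results$ani_ab[i]
    m[results$genome_b[i], results$genome_a[i]] <- results$ani_ba[i]
  }
  utils::write.table(cbind(genome = rownames(m), round(m, 1)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
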