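# Core/pan/specific-core set algebra over a family presence matrix.
# Presence means member count >= 1; copy number is ignored here.

check_group <- function(pm, strains, what = "group") {
  if (length(strains) == 0L)
    stop(what, " must contain at least one strain", call. = FALSE)
  miss <- setdiff(strains, colnames(pm))
  if (length(miss))
    stop(what, " strain(s) not in the matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Core families of a strain group
#'
#' Families with at least one member in *every* strain of the group.
#'
#' @param pm Presence matrix from [presence_matrix()].
#' @param strains Character vector of strain ids forming the group.
#' @return Sorted character vector of family ids.
#' @export
core_families <- function(pm, strains) {
  check_group(pm, strains)
  sub <- pm[, strains, drop = FALSE]
  sort(rownames(sub)[rowSums(sub >= 1L) == length(strains)])
}

#' Pan families of a strain group
#'
#' Families with at least one member in *at least one* strain of the
#' group.
#'
#' @inheritParams core_families
#' @return Sorted character vector of family ids.
#' @export
pan_families <- function(pm, strains) {
  check_group(pm, strains)
  sub <- pm[, strains, drop = FALSE]
  sort(rownames(sub)[rowSums(sub >= 1L) > 0L])
}

#' Group-specific core families
#'
#' Families in the core of the focal group and absent from the pan
#' genome of every other group: `core(focal) \\ pan(union(others))`.
#'
#' @param pm Presence matrix.
#' @param focal Character vector of focal-group strain ids.
#' @param others Character vector (or list of vectors) of all other
#'   strains; must be disjoint from `focal`. When empty, the focal core
#'   is returned unchanged.
#' @return Sorted character vector of family ids.
#' @export
specific_core <- function(pm, focal, others) {
  others <- unique(unlist(others))
  check_group(pm, focal, "focal group")
  overlap <- intersect(focal, others)
  if (length(overlap))
    stop("focal and other groups overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  core <- core_families(pm, focal)
  if (length(others) == 0L) return(core)
  check_group(pm, others, "other groups")
  sort(setdiff(core, pan_families(pm, others)))
}

#' Strain-specific family counts (flower-plot petals)
#'
#' For each strain, the number of families present in that strain and in
#' no other strain of the matrix.
#'
#' @param pm Presence matrix.
#' @return Named integer vector, one entry per strain (matrix column
#'   order).
#' @export
strain_unique_counts <- function(pm) {
  if (nrow(pm) == 0L)
    return(setNames(integer(ncol(pm)), colnames(pm)))
  present <- pm >= 1L
  n_strains <- rowSums(present)
  counts <- colSums(present & n_strains == 1L)
  setNames(as.integer(counts), colnames(pm))
}

#' Families retained in one group and lost in another
#'
#' Families with members in at least `min_retained_strains` strains of
#' the retained group (default: all of them) and no member in any strain
#' of the lost group. With the defaults this is the strict reading used
#' for phenotype comparisons: present in every retained genome, absent
#' without orthologs from every lost genome.
#'
#' @param pm Presence matrix.
#' @param retained,lost Disjoint, non-empty strain id vectors.
#' @param min_retained_strains Relaxation of the presence-in-all
#'   condition on the retained group.
#' @return Sorted character vector of family ids.
#' @export
lost_families <- function(pm, retained, lost,
                          min_retained_strains = length(retained)) {
  check_group(pm, retained, "retained group")
  check_group(pm, lost, "lost group")
  overlap <- intersect(retained, lost)
  if (length(overlap))
    stop("retained and lost groups overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  if (min_retained_strains < 1L || min_retained_strains > length(retained))
    stop("min_retained_strains must lie in [1, ", length(retained), "]",
         call. = FALSE)
  r <- pm[, retained, drop = FALSE]
  l <- pm[, lost, drop = FALSE]
  keep <- rowSums(r >= 1L) >= min_retained_strains & rowSums(l) == 0L
  sort(rownames(pm)[keep])
}

#' Helper: strain ids matching metadata filters
#'
#' @param metadata Strain metadata data frame.
#' @param cluster,phenotype Optional filters on `cluster_label` /
#'   `phenotype`.
#' @return Character vector of strain ids.
#' @export
strains_by <- function(metadata, cluster = NULL, phenotype = NULL) {
  keep <- rep(TRUE, nrow(metadata))
  if (!is.null(cluster)) keep <- keep & metadata$cluster_label %in% cluster
  if (!is.null(phenotype)) keep <- keep & metadata$phenotype %in% phenotype
  metadata$strain_id[keep]
}
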