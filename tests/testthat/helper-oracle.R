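# Independent oracles used by the tests. These deliberately share no code
# with the package: the Smith-Waterman oracle is a plain three-matrix
# affine-gap dynamic programme in R (score only), and the component oracle
# is a hand-written breadth-first search.

sw_score_oracle <- function(a, b, S = frankiapan::blosum62(),
                            gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                           X[i, j + 1] - gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                           Y[i + 1, j] - gap_extend)
    s <- S[A[i], B[j]]
    M[i + 1, j + 1] <- max(0, s + max(M[i, j], X[i, j], Y[i, j]))
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

bfs_components_oracle <- function(edges, loci) {
  adj <- setNames(vector("list", length(loci)), loci)
  for (k in seq_len(nrow(edges))) {
    a <- edges$locus_a[k]; b <- edges$locus_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(loci)), loci)
  comps <- list()
  for (v in loci) {
    if (seen[[v]]) next
    queue <- v; members <- character(0)
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (seen[[u]]) next
      seen[[u]] <- TRUE
      members <- c(members, u)
      queue <- c(queue, adj[[u]])
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

random_aa <- function(n, alphabet = "ACDEFGHIKLMNPQRSTVWY") {
  paste(sample(strsplit(alphabet, "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Small panel used by module tests (fast: ~100 proteins).
small_config <- function(seed = 1) {
  pangenome_config(
    groups = data.frame(
      group_id = c("ASpp", "ASpm", "B"),
      cluster_label = c("Ia", "Ia", "III"),
      phenotype = c("Sp+", "Sp-", "none"),
      n_strains = c(2L, 2L, 1L), stringsAsFactors = FALSE),
    n_universal_families = 4L, n_groupA_specific_core = 3L,
    n_lost_in_spplus = 5L, n_strain_specific_per_strain = 2L,
    protein_length_range = c(80L, 120L),
    within_family_divergence = 0.05, paralog_fraction = 0.4, seed = seed)
}

# Compare two family partitions as sets of locus sets.
partition_sets <- function(families) {
  unname(lapply(split(families$locus_id, families$family_id), sort))
}
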