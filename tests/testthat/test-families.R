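fake_hits <- function(q, s, q_start, q_end, s_start, s_end,
                      similarity, aligned = q_end - q_start + 1,
                      identity = similarity) {
  data.frame(query = q, subject = s, score = 100, evalue = 1e-30,
             q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end,
             aligned_cols = aligned, align_length = aligned,
             mismatches = 0, gap_opens = 0, gap_residues = 0,
             identity_fraction = identity, similarity_fraction = similarity,
             stringsAsFactors = FALSE)
}

test_that("edge rule boundaries: coverage inclusive, similarity strict", {
  # coverage exactly 0.80 on both sides, similarity clearly over -> edge
  h <- fake_hits("A", "B", 1, 80, 1, 80, similarity = 0.60)
  expect_false(is.null(edge_test(h, 100, 100)))
  # coverage 0.79 on one side -> no edge
  h2 <- fake_hits("A", "B", 1, 79, 1, 80, similarity = 0.60)
  expect_null(edge_test(h2, 100, 100))
  # similarity exactly 0.50 -> no edge ("over 50%" is strict)
  h3 <- fake_hits("A", "B", 1, 90, 1, 90, similarity = 0.50)
  expect_null(edge_test(h3, 100, 100))
  expect_false(is.null(edge_test(
    fake_hits("A", "B", 1, 90, 1, 90, similarity = 0.5001), 100, 100)))
})

test_that("multi-HSP coverage unions and similarity weights combine", {
  h <- rbind(fake_hits("A", "B", 1, 50, 1, 50, similarity = 0.9),
             fake_hits("A", "B", 41, 90, 41, 90, similarity = 0.4))
  e <- edge_test(h, 100, 100)
  expect_false(is.null(e))
  expect_equal(e$coverage_a, 0.9)
  expect_equal(e$similarity, (50 * 0.9 + 50 * 0.4) / 100)
})

test_that("families are connected components with singletons preserved", {
  loci <- c("A", "B", "C", "D", "E")
  no_edges <- data.frame(locus_a = character(0), locus_b = character(0))
  f <- build_families(no_edges, loci)
  expect_equal(nrow(f), 5L)
  expect_equal(length(unique(f$family_id)), 5L)

  e <- data.frame(locus_a = c("A", "B"), locus_b = c("B", "C"))
  f <- build_families(e, loci)
  expect_setequal(f$locus_id[f$family_id == "A"], c("A", "B", "C"))
  expect_equal(sort(unique(f$family_id)), c("A", "D", "E"))
  expect_error(build_families(
    data.frame(locus_a = "Z", locus_b = "A"), loci), "Z")
})

test_that("components match a breadth-first-search oracle on random graphs", {
  withr::with_seed(31, {
    for (k in 1:10) {
      loci <- paste0("L", sprintf("%02d", 1:15))
      n_e <- sample(0:12, 1)
      e <- data.frame(locus_a = sample(loci, n_e, replace = TRUE),
                      locus_b = sample(loci, n_e, replace = TRUE),
                      stringsAsFactors = FALSE)
      e <- e[e$locus_a != e$locus_b, , drop = FALSE]
      got <- partition_sets(build_families(e, loci))
      want <- bfs_components_oracle(e, loci)
      expect_true(setequal(got, want), info = paste("graph", k))
    }
  })
})

test_that("presence matrix counts members, including paralogs", {
  md <- data.frame(strain_id = "s1", cluster_label = "Ia", phenotype = "Sp-")
  fam <- data.frame(family_id = c("F1", "F2", "F3"), strain_id = "s1",
                    locus_id = c("a", "b", "c"))
  pm <- presence_matrix(fam, md)
  expect_equal(dim(pm), c(3L, 1L))
  expect_true(all(pm == 1L))

  fam2 <- data.frame(family_id = c("F1", "F1"), strain_id = "s1",
                     locus_id = c("a", "a2"))
  expect_equal(presence_matrix(fam2, md)["F1", "s1"], 2L)
  expect_error(presence_matrix(
    data.frame(family_id = "F", strain_id = "s9", locus_id = "x"), md), "s9")
})

test_that("families recover the planted partition and column sums match", {
  sim <- generate_pangenome(small_config(seed = 3))
  run <- run_pipeline(sim$panel)
  expect_true(setequal(partition_sets(run$families),
                       partition_sets(sim$truth$families)))
  np <- lengths(sim$panel$proteomes)
  expect_equal(colSums(run$presence)[names(np)], np[names(np)],
               ignore_attr = TRUE)
})

test_that("raising the similarity threshold only refines families", {
  sim <- generate_pangenome(small_config(seed = 12))
  panel <- sim$panel
  hits <- all_vs_all_hits(panel)
  loci <- panel_loci(panel)
  lens <- setNames(loci$length, loci$locus_id)
  loose <- build_families(homology_edges(hits, lens, similarity_min = 0.50),
                          loci[, c("strain_id", "locus_id")])
  strict <- build_families(homology_edges(hits, lens, similarity_min = 0.90),
                           loci[, c("strain_id", "locus_id")])
  loose_of <- setNames(loose$family_id, loose$locus_id)
  # every strict family sits inside one loose family
  for (f in unique(strict$family_id)) {
    members <- strict$locus_id[strict$family_id == f]
    expect_equal(length(unique(loose_of[members])), 1L)
  }
  # and the locus universe is partitioned either way
  expect_setequal(strict$locus_id, loci$locus_id)
  expect_false(anyDuplicated(strict$locus_id) > 0)
})
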