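test_that("BLOSUM62 is symmetric, complete and matches the reference matrix", {
  m <- blosum62()
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_true(all(std %in% rownames(m)))
  expect_identical(m, t(m))
  expect_true(all(diag(m[std, std]) > 0))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  ref <- e$BLOSUM62[rownames(m), colnames(m)]
  storage.mode(ref) <- "integer"
  expect_true(all(m == ref))
})

test_that("NCBI-format matrix text round-trips", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_substitution_matrix(blosum62(), path)
  m2 <- read_substitution_matrix(path, name = "BLOSUM62")
  expect_true(all(m2 == blosum62()))
  expect_identical(rownames(m2), rownames(blosum62()))
})

test_that("self-alignment yields one full-length perfect hit", {
  h <- local_align("HEAGAWGHEE", "HEAGAWGHEE")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1, 10, 1, 10))
  expect_equal(h$identity_fraction, 1)
  expect_equal(h$similarity_fraction, 1)
})

test_that("local scores match the exhaustive DP oracle and Biostrings", {
  p <- alignment_params(evalue_threshold = 1e9)
  h <- local_align("HEAGAWGHEE", "PAWHEAE", params = p)
  expect_equal(max(h$score), sw_score_oracle("HEAGAWGHEE", "PAWHEAE"))
  pa <- Biostrings::pairwiseAlignment(
    "HEAGAWGHEE", "PAWHEAE", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, type = "local")
  expect_equal(max(h$score), Biostrings::score(pa))

  withr::with_seed(7, {
    for (k in 1:40) {
      a <- random_aa(sample(5:30, 1)); b <- random_aa(sample(5:30, 1))
      got <- local_align(a, b, params = p)
      expect_equal(max(c(0, got$score)), sw_score_oracle(a, b),
                   info = paste("pair", k))
    }
  })
})

test_that("top-hit score is symmetric in its arguments", {
  p <- alignment_params(evalue_threshold = 1e9)
  withr::with_seed(11, {
    anc <- random_aa(60)
    for (k in 1:10) {
      a <- mutate_protein(anc, 0.2)
      b <- mutate_protein(anc, 0.2)
      expect_equal(max(local_align(a, b, params = p)$score),
                   max(local_align(b, a, params = p)$score))
    }
  })
})

test_that("identity fraction never exceeds similarity fraction", {
  withr::with_seed(3, {
    anc <- random_aa(120)
    for (k in 1:15) {
      h <- local_align(mutate_protein(anc, 0.25), mutate_protein(anc, 0.25),
                       params = alignment_params(evalue_threshold = 10))
      expect_true(all(h$identity_fraction <= h$similarity_fraction + 1e-12))
    }
  })
})

test_that("random unrelated 50-mers almost never produce significant hits", {
  withr::with_seed(19, {
    n_hit <- 0L
    for (k in 1:100) {
      h <- local_align(random_aa(50), random_aa(50))
      if (nrow(h) > 0L) n_hit <- n_hit + 1L
    }
    expect_lte(n_hit, 2L)
  })
})

test_that("unknown residues are rejected with locus and position", {
  expect_error(local_align("ACDE1", "ACDE"), "position 5")
  expect_error(local_align("ACDE", "AC*DE", id_b = "locusB"), "locusB")
})

test_that("Karlin-Altschul E-value follows the closed form", {
  p <- alignment_params()
  expect_equal(karlin_evalue(40, 100, 100, p),
               0.041 * 100 * 100 * exp(-0.267 * 40))
  expect_equal(karlin_evalue(0, 50, 80, p), p$karlin_K * 50 * 80)
  expect_lt(karlin_evalue(41, 100, 100, p), karlin_evalue(40, 100, 100, p))
  expect_error(karlin_evalue(10, 0, 100, p), "lengths")
})

test_that("coverage is the union of HSP intervals", {
  one <- data.frame(q_start = 1, q_end = 80, s_start = 1, s_end = 80)
  expect_equal(coverage_fraction(one, 100, "query"), 0.80)
  two <- data.frame(q_start = c(1, 41), q_end = c(50, 90),
                    s_start = c(1, 41), s_end = c(50, 90))
  expect_equal(coverage_fraction(two, 100, "query"), 0.90)
  expect_equal(coverage_fraction(two[0, ], 100, "query"), 0)
  bad <- data.frame(q_start = 0, q_end = 10, s_start = 1, s_end = 10)
  expect_error(coverage_fraction(bad, 100, "query"), "span")
})

test_that("global percent identity handles identity, divergence and disagreement", {
  expect_equal(global_percent_identity("HEAGAWGHEE", "HEAGAWGHEE"), 100)
  expect_equal(global_percent_identity("ACDE", "ACDF"), 75)
  expect_equal(global_percent_identity("AAAA", "WWWW"), 0)
  expect_error(global_percent_identity("", "ACDE"), "empty")
})

test_that("self-hits dominate in an all-vs-all run", {
  withr::with_seed(23, {
    anc <- random_aa(100)
    seqs <- c(a = mutate_protein(anc, 0.1), b = mutate_protein(anc, 0.1),
              c = random_aa(90))
    h <- all_vs_all_hits(seqs, prefilter = FALSE)
    for (id in names(seqs)) {
      mine <- h[h$query == id | h$subject == id, ]
      self <- mine[mine$query == id & mine$subject == id, ]
      expect_equal(nrow(self), 1L)
      expect_equal(min(mine$evalue), self$evalue)
    }
  })
})

test_that("the k-mer prefilter does not change family-relevant hits", {
  withr::with_seed(29, {
    anc1 <- random_aa(110); anc2 <- random_aa(130)
    seqs <- c(a1 = mutate_protein(anc1, 0.05), a2 = mutate_protein(anc1, 0.05),
              b1 = mutate_protein(anc2, 0.05), b2 = mutate_protein(anc2, 0.05),
              x = random_aa(100))
    with_pf <- all_vs_all_hits(seqs, prefilter = TRUE)
    without <- all_vs_all_hits(seqs, prefilter = FALSE)
    key <- function(h) sort(paste(h$query, h$subject, h$score, h$q_start))
    expect_identical(key(with_pf), key(without))
  })
})

test_that("hits export as 12-column tabular text", {
  h <- local_align("HEAGAWGHEE", "HEAGAWGHEE")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, path)
  got <- read.delim(path, header = FALSE)
  expect_equal(ncol(got), 12L)
  expect_equal(got$V7, 1)   # qstart, 1-based
  expect_equal(got$V8, 10)
})
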