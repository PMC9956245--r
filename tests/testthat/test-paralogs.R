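test_that("exact within-genome duplicates are called symmetrically", {
  withr::with_seed(41, {
    seq <- random_aa(120)
    proteome <- c(g1 = seq, g2 = seq, g3 = random_aa(110))
    expect_identical(detect_paralogs("g1", proteome), "g2")
    expect_identical(detect_paralogs("g2", proteome), "g1")
    expect_length(detect_paralogs("g3", proteome), 0)
    expect_error(detect_paralogs("nope", proteome), "not in the proteome")
  })
})

test_that("highly diverged copies fall below the identity rule", {
  withr::with_seed(43, {
    seq <- random_aa(150)
    far <- mutate_protein(seq, 0.75)   # ~25% positional identity
    proteome <- c(g1 = seq, g2 = far)
    expect_length(detect_paralogs("g1", proteome), 0)
  })
})

test_that("truncated duplicates fall below the coverage rule", {
  withr::with_seed(47, {
    seq <- random_aa(200)
    trunc <- substr(seq, 1, 80)        # 40% of the query at ~100% identity
    proteome <- c(g1 = seq, g2 = trunc)
    expect_length(detect_paralogs("g1", proteome), 0)
    # but a 60% fragment passes (> 50% coverage, identity ~1)
    proteome2 <- c(g1 = seq, g2 = substr(seq, 1, 120))
    expect_identical(detect_paralogs("g1", proteome2), "g2")
  })
})

test_that("paralog thresholds are strict at both boundaries", {
  base <- data.frame(query = "a", subject = "b", score = 500, evalue = 1e-40,
                     q_start = 1, q_end = 50, s_start = 1, s_end = 50,
                     aligned_cols = 50, align_length = 50, mismatches = 0,
                     gap_opens = 0, gap_residues = 0,
                     identity_fraction = 0.30, similarity_fraction = 0.6,
                     stringsAsFactors = FALSE)
  lens <- c(a = 100, b = 100)
  strains <- c(a = "s1", b = "s1")
  # coverage 50/100 = 0.50 exactly and identity 0.30 exactly: both rejected
  expect_equal(nrow(paralog_pairs_from_hits(base, lens, strains)), 0L)
  ok <- base; ok$q_end <- 51; ok$s_end <- 51; ok$identity_fraction <- 0.301
  expect_equal(nrow(paralog_pairs_from_hits(ok, lens, strains)), 2L)
  # identity still at the boundary fails even with full coverage
  id_edge <- base; id_edge$q_end <- 100; id_edge$s_end <- 100
  expect_equal(nrow(paralog_pairs_from_hits(id_edge, lens, strains)), 0L)
  # cross-strain pairs are never paralogs
  cross <- ok; strains2 <- c(a = "s1", b = "s2")
  expect_equal(nrow(paralog_pairs_from_hits(cross, lens, strains2)), 0L)
})

test_that("copy-number classification is total and member-driven", {
  fam <- data.frame(family_id = c("L1", "L1", "L2"),
                    strain_id = c("r1", "r2", "r1"),
                    locus_id = c("x1", "x2", "y1"))
  calls <- list(x1 = "x9", x2 = character(0), y1 = character(0))
  got <- classify_copy_number(c("L1", "L2"), fam, calls, c("r1", "r2"))
  expect_identical(got[["L1"]], "several_copies")
  expect_identical(got[["L2"]], "single_copy")
  expect_setequal(names(got), c("L1", "L2"))
  expect_error(classify_copy_number("L1", fam, list(x1 = "x9"), c("r1", "r2")),
               "missing")
})

test_that("planted duplicated lost families are classified several_copies", {
  sim <- generate_pangenome(small_config(seed = 13))
  run <- run_pipeline(sim$panel)
  truth <- sim$truth
  # families whose planted paralog copy sits in a retained (Sp-) strain
  md <- sim$panel$metadata
  spm <- md$strain_id[md$phenotype == "Sp-"]
  fam_of <- setNames(truth$families$family_id, truth$families$locus_id)
  dup_fams <- unique(fam_of[truth$paralog_pairs$locus_b[
    truth$paralog_pairs$strain_id %in% spm]])
  lost_truth <- unique(truth$families$family_id[
    truth$families$role == "lost_in_spplus"])
  expected_several <- intersect(dup_fams, lost_truth)
  # translate planted family ids to recovered ids via any member locus
  rec_of <- setNames(run$families$family_id, run$families$locus_id)
  to_rec <- function(f) unique(rec_of[truth$families$locus_id[
    truth$families$family_id == f]])
  rec_several <- unlist(lapply(expected_several, to_rec))
  got_several <- names(run$copy_class)[run$copy_class == "several_copies"]
  expect_setequal(got_several, rec_several)
  # 40% of 5 planted lost families -> exactly 2 duplicated
  expect_length(got_several, 2L)
})

test_that("lost-family summaries count COG, localization and paralogy", {
  rec <- lost_family_annotations()
  expect_equal(nrow(rec), 88L)
  s <- summarize_lost_families(rec)
  expect_equal(s$total, 88L)
  expect_equal(sum(s$cog_counts), 88L)
  expect_lte(s$tm_or_sp$count, s$total)
  expect_lte(s$with_paralogs$count, s$total)
  expect_equal(unname(s$cog_percents[["K"]]),
               round(100 * s$cog_counts[["K"]] / 88, 1))
  one <- data.frame(cog = "K", locus = "X", gene = "", product = "p",
                    paralogs = "", localization = "SP")
  s1 <- summarize_lost_families(one)
  expect_equal(s1$tm_or_sp$count, 1L)
  expect_equal(s1$tm_or_sp$percent, 100)
  expect_error(summarize_lost_families(one[0, ]), "no annotation")
})

test_that("annotation tables are validated on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cog\tlocus\tgene\tproduct\tparalogs\tlocalization",
               "K\tA\t\tp\t\tSP", "K\tA\t\tp\t\tTM"), path)
  expect_error(read_annotation_table(path), "duplicate locus")
  writeLines(c("cog\tlocus\tgene\tproduct\tparalogs\tlocalization",
               "K\tA\t\tp\t\tOUTER"), path)
  expect_error(read_annotation_table(path), "localization")
})
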