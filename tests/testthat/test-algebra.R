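toy_pm <- function() {
  md <- data.frame(
    strain_id = c("a1", "a2", "a3", "b1", "b2"),
    cluster_label = c("Ia", "Ia", "Ia", "Ic", "Ic"),
    phenotype = c("Sp-", "Sp-", "Sp+", "none", "none"))
  m <- matrix(0L, 6, 5, dimnames = list(
    c("F1", "F2", "F3", "F4", "F5", "F6"), md$strain_id))
  m["F1", ] <- 1L                      # universal
  m["F2", c("a1", "a2", "a3")] <- 1L   # core of A, absent in B
  m["F3", c("a1", "a2")] <- 1L         # core of Sp- only
  m["F4", "a1"] <- 1L                  # strain-specific
  m["F5", c("a1", "b1")] <- 1L         # shared across groups
  m["F6", c("b1", "b2")] <- 2L         # outgroup family, multi-copy
  attr(m, "metadata") <- md
  m
}

test_that("core requires presence in every strain of the group", {
  pm <- toy_pm()
  expect_setequal(core_families(pm, c("a1", "a2", "a3")), c("F1", "F2"))
  # one strain alone: core = its own repertoire
  expect_setequal(core_families(pm, "a1"), c("F1", "F2", "F3", "F4", "F5"))
  # family absent in exactly one group strain is excluded
  expect_false("F3" %in% core_families(pm, c("a1", "a2", "a3")))
  expect_error(core_families(pm, character(0)), "at least one")
})

test_that("pan is the union of repertoires", {
  pm <- toy_pm()
  expect_setequal(pan_families(pm, "b1"), c("F1", "F5", "F6"))
  expect_setequal(pan_families(pm, c("b1", "b2")), c("F1", "F5", "F6"))
  expect_identical(pan_families(pm, "a2"), core_families(pm, "a2"))
})

test_that("specific core subtracts the outgroup pan", {
  pm <- toy_pm()
  expect_setequal(specific_core(pm, c("a1", "a2", "a3"), c("b1", "b2")), "F2")
  # empty others: returns the focal core unchanged
  expect_setequal(specific_core(pm, c("a1", "a2", "a3"), character(0)),
                  c("F1", "F2"))
  # a focal-core family present in one outgroup strain is excluded
  expect_false("F1" %in% specific_core(pm, c("a1", "a2", "a3"), c("b1", "b2")))
  expect_error(specific_core(pm, c("a1", "a2"), c("a2", "b1")), "overlap")
})

test_that("flower-plot petals count families found in exactly one strain", {
  pm <- toy_pm()
  petals <- strain_unique_counts(pm)
  expect_equal(petals[["a1"]], 1L)  # F4 only; F5 is in two strains
  expect_equal(petals[["b1"]], 0L)
  expect_equal(sum(petals), 1L)
})

test_that("lost families are present in all retained, absent from all lost", {
  pm <- toy_pm()
  # strict default: F4 and F5 miss one retained strain, F6 misses both
  expect_identical(lost_families(pm, retained = c("a1", "a2"), lost = "a3"),
                   "F3")
  # relaxed to any retained strain: F4 and F5 come back, F6 still absent
  expect_setequal(lost_families(pm, c("a1", "a2"), "a3",
                                min_retained_strains = 1),
                  c("F3", "F4", "F5"))
  # identical repertoires in both groups -> empty set
  ident <- matrix(1L, 2, 2, dimnames = list(c("F1", "F2"), c("x", "y")))
  expect_length(lost_families(ident, "x", "y"), 0)
  expect_error(lost_families(pm, c("a1", "a2"), c("a2")), "overlap")
  expect_error(lost_families(pm, c("a1"), "a3", min_retained_strains = 5),
               "min_retained_strains")
})

test_that("set-algebra invariants hold on random presence matrices", {
  withr::with_seed(37, {
    for (k in 1:20) {
      n_f <- sample(3:12, 1); n_s <- sample(3:6, 1)
      m <- matrix(rbinom(n_f * n_s, 2, 0.5), n_f, n_s,
                  dimnames = list(paste0("F", 1:n_f), paste0("s", 1:n_s)))
      m <- m[rowSums(m) > 0, , drop = FALSE]
      if (nrow(m) < 2) next
      g1 <- colnames(m)[1:2]; g2 <- setdiff(colnames(m), g1)
      expect_true(all(core_families(m, g1) %in% pan_families(m, g1)))
      expect_true(all(specific_core(m, g1, g2) %in% core_families(m, g1)))
      if (length(g2)) {
        la <- lost_families(m, g1, g2)
        lb <- lost_families(m, g2, g1)
        expect_length(intersect(la, lb), 0)
        expect_length(intersect(la, pan_families(m, g2)), 0)
        # adding a strain never grows the core, never shrinks the pan
        g1p <- c(g1, g2[1])
        expect_true(all(core_families(m, g1p) %in% core_families(m, g1)))
        expect_true(all(pan_families(m, g1) %in% pan_families(m, g1p)))
      }
    }
  })
})

test_that("planted pangenome structure is recovered exactly", {
  sim <- generate_pangenome(small_config(seed = 21))
  run <- run_pipeline(sim$panel)
  truth <- sim$truth$families
  # map recovered families to planted roles via member loci
  role_of <- setNames(truth$role, truth$locus_id)
  rec_role <- function(ids) {
    members <- run$families$locus_id[run$families$family_id %in% ids]
    unique(role_of[members])
  }
  expect_identical(unname(rec_role(run$specific_core)), "groupA_core_specific")
  expect_length(run$specific_core, 3L)
  expect_identical(unname(rec_role(run$lost)), "lost_in_spplus")
  expect_length(run$lost, 5L)
  md <- sim$panel$metadata
  expect_equal(unname(run$strain_unique[md$strain_id]),
               rep(2L, nrow(md)))
})
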