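#' Synthetic pangenome configuration
#'
#' Describes a multi-group strain panel with planted family structure.
#' The defaults mirror the study conditions this package targets at desk
#' scale: a focal cluster ("Ia") of 12 strains split 6 sporulating (Sp+)
#' / 6 non-sporulating (Sp-), two outgroup strains for each of four
#' other clusters, 9 focal-cluster-specific core families, 88 families
#' retained in all Sp- strains and absent from every Sp+ strain, 15
#' universal families, 5 strain-specific decoys per strain, 5%
#' within-family divergence and a 27% paralog fraction.
#'
#' @param groups Data frame with columns `group_id`, `cluster_label`,
#'   `phenotype` (one of `"Sp+"`, `"Sp-"`, `"none"`) and `n_strains`.
#'   The cluster label of the *first* row defines the focal cluster used
#'   for group-specific core families.
#' @param n_universal_families Families present in every strain.
#' @param n_groupA_specific_core Families present in all focal-cluster
#'   strains and absent elsewhere.
#' @param n_lost_in_spplus Families present in all Sp- strains and in no
#'   Sp+ strain.
#' @param n_strain_specific_per_strain Fresh random singleton decoys per
#'   strain.
#' @param protein_length_range Integer min/max ancestral protein length
#'   (residues).
#' @param within_family_divergence Per-member substitution fraction in
#'   \[0, 0.5); each member is the family ancestor mutated at this rate,
#'   so mean within-family identity stays >= 1 - 2*divergence.
#' @param paralog_fraction Fraction of families (per role) that receive
#'   a within-genome duplicate copy in their first member strain.
#' @param seed Integer seed; equal seeds give byte-identical panels.
#' @return A validated list of class `pangenome_config`.
#' @export
pangenome_config <- function(groups = default_groups(),
                             n_universal_families = 15L,
                             n_groupA_specific_core = 9L,
                             n_lost_in_spplus = 88L,
                             n_strain_specific_per_strain = 5L,
                             protein_length_range = c(100L, 200L),
                             within_family_divergence = 0.05,
                             paralog_fraction = 0.27,
                             seed = 1L) {
  cfg <- list(groups = groups,
              n_universal_families = as.integer(n_universal_families),
              n_groupA_specific_core = as.integer(n_groupA_specific_core),
              n_lost_in_spplus = as.integer(n_lost_in_spplus),
              n_strain_specific_per_strain =
                as.integer(n_strain_specific_per_strain),
              protein_length_range = as.integer(protein_length_range),
              within_family_divergence = within_family_divergence,
              paralog_fraction = paralog_fraction,
              seed = as.integer(seed))
  bad <- function(field, why)
    stop("invalid pangenome_config field '", field, "': ", why, call. = FALSE)
  g <- cfg$groups
  if (!is.data.frame(g) ||
      !all(c("group_id", "cluster_label", "phenotype", "n_strains") %in% names(g)))
    bad("groups", "need columns group_id, cluster_label, phenotype, n_strains")
  if (nrow(g) && !all(g$phenotype %in% c("Sp+", "Sp-", "none")))
    bad("groups", "phenotype must be one of Sp+, Sp-, none")
  if (nrow(g) && (anyDuplicated(g$group_id) || any(g$n_strains < 0)))
    bad("groups", "group ids must be unique and n_strains >= 0")
  for (f in c("n_universal_families", "n_groupA_specific_core",
              "n_lost_in_spplus", "n_strain_specific_per_strain"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) bad(f, "must be a count >= 0")
  if (length(cfg$protein_length_range) != 2L ||
      any(cfg$protein_length_range < 10L) ||
      diff(cfg$protein_length_range) < 0L)
    bad("protein_length_range", "need min <= max, both >= 10")
  if (!is.numeric(cfg$within_family_divergence) ||
      cfg$within_family_divergence < 0 || cfg$within_family_divergence >= 0.5)
    bad("within_family_divergence", "must lie in [0, 0.5)")
  if (cfg$paralog_fraction < 0 || cfg$paralog_fraction > 1)
    bad("paralog_fraction", "must lie in [0, 1]")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  structure(cfg, class = "pangenome_config")
}

#' @rdname pangenome_config
#' @export
default_groups <- function() {
  data.frame(
    group_id = c("IaSpp", "IaSpm", "Ic", "II", "III", "IV"),
    cluster_label = c("Ia", "Ia", "Ic", "II", "III", "IV"),
    phenotype = c("Sp+", "Sp-", "none", "none", "none", "none"),
    n_strains = c(6L, 6L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

random_protein <- function(len) {
  paste(sample(strsplit(AA_STANDARD, "")[[1]], len, replace = TRUE),
        collapse = "")
}

#' Mutate a protein at a fixed substitution fraction
#'
#' Substitutes `round(divergence * nchar(seq))` positions, chosen
#' uniformly without replacement; each replacement residue is drawn
#' uniformly from the 19 other standard residues, so every mutated
#' position differs from the input. Length is preserved; no indels.
#'
#' @param seq Protein sequence over the 20 standard residues.
#' @param divergence Substitution fraction in \[0, 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used (callers such as [generate_pangenome()] seed once globally).
#' @return Mutated sequence.
#' @export
mutate_protein <- function(seq, divergence, seed = NULL) {
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)", call. = FALSE)
  if (!nzchar(seq)) stop("sequence must be non-empty", call. = FALSE)
  check_residues(seq, AA_STANDARD, "sequence")
  run <- function() {
    chars <- strsplit(seq, "")[[1]]
    aa <- strsplit(AA_STANDARD, "")[[1]]
    k <- round(divergence * length(chars))
    if (k > 0) {
      pos <- sample(length(chars), k)
      for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1L)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

mutate_dna <- function(seq, n_subs) {
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  if (n_subs > 0) {
    pos <- sample(length(chars), n_subs)
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a nucleotide genome pair at a controlled substitution rate
#'
#' `seqA` is uniform random ACGT; `seqB` is `seqA` with exactly
#' `round(substitution_rate * length)` positions substituted to a
#' different base. The minimum length of 2040 bp guarantees at least two
#' 1020-bp ANI fragments.
#'
#' @param length Genome length in bp (>= 2040).
#' @param substitution_rate Fraction in \[0, 0.3).
#' @param seed Integer seed.
#' @return `list(seqA =, seqB =)` of nucleotide strings.
#' @export
generate_genome_pair <- function(length, substitution_rate, seed = 1L) {
  if (length < 2040)
    stop("length must be >= 2040 bp (two ANI fragments)", call. = FALSE)
  if (!is.numeric(substitution_rate) || substitution_rate < 0 ||
      substitution_rate >= 0.3)
    stop("substitution_rate must lie in [0, 0.3)", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    seqA <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
    seqB <- mutate_dna(seqA, round(substitution_rate * length))
    list(seqA = seqA, seqB = seqB)
  })
}

#' Generate a synthetic multi-strain pangenome with planted truth
#'
#' Every planted family has one ancestral sequence; each member (and each
#' planted paralog copy) is that ancestor independently mutated at the
#' configured divergence, so within-family identity is controlled
#' analytically without alignment. Strain-specific decoys are fresh
#' i.i.d. random sequences (expected pairwise identity ~5%, far below
#' every edge threshold). Family roles:
#' \describe{
#'   \item{universal}{members in every strain;}
#'   \item{groupA_core_specific}{members in all focal-cluster strains,
#'     none elsewhere;}
#'   \item{lost_in_spplus}{members in all Sp- strains, none in any Sp+
#'     strain;}
#'   \item{strain_specific}{a single member in one strain.}
#' }
#'
#' @param config A [pangenome_config()].
#' @return A list with elements `panel` (a [strain_panel()]) and `truth`
#'   (list with `families`, a data frame of `family_id`, `role`,
#'   `strain_id`, `locus_id`; and `paralog_pairs`, a data frame of
#'   `strain_id`, `locus_a`, `locus_b`).
#' @export
generate_pangenome <- function(config = pangenome_config()) {
  if (!inherits(config, "pangenome_config"))
    config <- do.call(pangenome_config, config)
  g <- config$groups
  strains <- data.frame(strain_id = character(0), cluster_label = character(0),
                        phenotype = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    n <- g$n_strains[i]
    if (n == 0L) next
    strains <- rbind(strains, data.frame(
      strain_id = sprintf("%s_%02d", g$group_id[i], seq_len(n)),
      cluster_label = g$cluster_label[i], phenotype = g$phenotype[i],
      stringsAsFactors = FALSE))
  }
  focal_cluster <- if (nrow(g)) g$cluster_label[1L] else NA_character_
  focal <- strains$strain_id[strains$cluster_label %in% focal_cluster]
  spm <- strains$strain_id[strains$phenotype == "Sp-"]
  spp <- strains$strain_id[strains$phenotype == "Sp+"]

  withr::with_seed(config$seed, {
    proteomes <- setNames(
      replicate(nrow(strains), character(0), simplify = FALSE),
      strains$strain_id)
    counter <- setNames(integer(nrow(strains)), strains$strain_id)
    fam_rows <- list()
    para_rows <- list()
    next_locus <- function(strain) {
      counter[[strain]] <<- counter[[strain]] + 1L
      sprintf("%s_g%04d", strain, counter[[strain]])
    }
    lr <- config$protein_length_range
    plant <- function(role, fam_ids, member_strains_list) {
      n_para <- round(config$paralog_fraction * length(fam_ids))
      for (k in seq_along(fam_ids)) {
        len <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
        anc <- random_protein(len)
        members <- member_strains_list[[k]]
        for (s in members) {
          loc <- next_locus(s)
          proteomes[[s]][loc] <<-
            mutate_protein(anc, config$within_family_divergence)
          fam_rows[[length(fam_rows) + 1L]] <<-
            data.frame(family_id = fam_ids[k], role = role, strain_id = s,
                       locus_id = loc, stringsAsFactors = FALSE)
        }
        if (k <= n_para && length(members)) {
          s <- members[1L]  # duplicate goes into the first member strain
          orig <- fam_rows[[length(fam_rows) - length(members) + 1L]]$locus_id
          loc <- next_locus(s)
          proteomes[[s]][loc] <<-
            mutate_protein(anc, config$within_family_divergence)
          fam_rows[[length(fam_rows) + 1L]] <<-
            data.frame(family_id = fam_ids[k], role = role, strain_id = s,
                       locus_id = loc, stringsAsFactors = FALSE)
          para_rows[[length(para_rows) + 1L]] <<-
            data.frame(strain_id = s, locus_a = orig, locus_b = loc,
                       stringsAsFactors = FALSE)
        }
      }
    }
    all_strains <- strains$strain_id
    if (config$n_universal_families > 0L && length(all_strains))
      plant("universal",
            sprintf("U%04d", seq_len(config$n_universal_families)),
            rep(list(all_strains), config$n_universal_families))
    if (config$n_groupA_specific_core > 0L && length(focal))
      plant("groupA_core_specific",
            sprintf("S%04d", seq_len(config$n_groupA_specific_core)),
            rep(list(focal), config$n_groupA_specific_core))
    if (config$n_lost_in_spplus > 0L && length(spm))
      plant("lost_in_spplus",
            sprintf("L%04d", seq_len(config$n_lost_in_spplus)),
            rep(list(spm), config$n_lost_in_spplus))
    if (config$n_strain_specific_per_strain > 0L) {
      k <- 0L
      for (s in all_strains) for (i in seq_len(config$n_strain_specific_per_strain)) {
        k <- k + 1L
        len <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
        loc <- next_locus(s)
        proteomes[[s]][loc] <- random_protein(len)
        fam_rows[[length(fam_rows) + 1L]] <-
          data.frame(family_id = sprintf("X%04d", k), role = "strain_specific",
                     strain_id = s, locus_id = loc, stringsAsFactors = FALSE)
      }
    }
    families <- if (length(fam_rows)) do.call(rbind, fam_rows) else
      data.frame(family_id = character(0), role = character(0),
                 strain_id = character(0), locus_id = character(0),
                 stringsAsFactors = FALSE)
    paralog_pairs <- if (length(para_rows)) do.call(rbind, para_rows) else
      data.frame(strain_id = character(0), locus_a = character(0),
                 locus_b = character(0), stringsAsFactors = FALSE)
    rownames(families) <- rownames(paralog_pairs) <- NULL
    list(panel = strain_panel(proteomes, strains),
         truth = list(families = families, paralog_pairs = paralog_pairs),
         config = config)
  })
}

#' Write a generated pangenome to disk
#'
#' One protein FASTA per strain (headers `strain|locus`), a strain
#' metadata TSV and the planted-truth tables.
#'
#' @param sim Result of [generate_pangenome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pangenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- sim$panel
  for (s in names(panel$proteomes)) {
    p <- panel$proteomes[[s]]
    p <- p[order(names(p))]
    if (length(p)) {
      x <- Biostrings::AAStringSet(p)
      names(x) <- paste0(s, "|", names(p))
    } else x <- Biostrings::AAStringSet()
    Biostrings::writeXStringSet(x, file.path(dir, paste0(s, ".faa")))
  }
  utils::write.table(panel$metadata, file.path(dir, "strains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$families, file.path(dir, "truth_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$paralog_pairs,
                     file.path(dir, "truth_paralogs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
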