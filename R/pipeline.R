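#' Pipeline configuration
#'
#' Houses every threshold of the comparative-pangenomics chain in one
#' declarative object: the homology-search E-value cutoff (1e-4), the
#' family rule (HSP-union coverage >= 80% on both proteins, positive-
#' score similarity > 50%), the paralog rule (query coverage > 50%,
#' identity > 30%, both strict), the ANI species threshold (95%) and the
#' GC contamination cutoff (reads at <= 54% GC removed).
#'
#' @param evalue_threshold Homology significance cutoff.
#' @param family_coverage Minimum HSP-union coverage on both partners.
#' @param family_similarity Similarity threshold (strict).
#' @param paralog_coverage Paralog query-coverage threshold (strict).
#' @param paralog_identity Paralog identity threshold (strict).
#' @param ani_threshold Species delineation threshold, percent.
#' @param gc_filter_max GC fraction at or below which a read is removed.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param focal_cluster Cluster label defining the focal group.
#' @param retained_phenotype,lost_phenotype Phenotype labels defining
#'   the retained / lost comparison groups.
#' @param min_retained_strains Optional relaxation for [lost_families()]
#'   (`NULL` = all retained strains).
#' @param prefilter Apply the shared k-mer pair prefilter in the
#'   all-vs-all stage.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_threshold = 1e-4,
                            family_coverage = 0.80,
                            family_similarity = 0.50,
                            paralog_coverage = 0.50,
                            paralog_identity = 0.30,
                            ani_threshold = 95,
                            gc_filter_max = 0.54,
                            gap_open = 11, gap_extend = 1,
                            focal_cluster = "Ia",
                            retained_phenotype = "Sp-",
                            lost_phenotype = "Sp+",
                            min_retained_strains = NULL,
                            prefilter = TRUE,
                            seed = 1L) {
  in01 <- function(x) is.numeric(x) && x >= 0 && x <= 1
  if (evalue_threshold <= 0) stop("evalue_threshold must be > 0", call. = FALSE)
  if (!in01(family_coverage) || !in01(family_similarity) ||
      !in01(paralog_coverage) || !in01(paralog_identity) ||
      !in01(gc_filter_max))
    stop("fraction thresholds must lie in [0, 1]", call. = FALSE)
  if (ani_threshold < 0 || ani_threshold > 100)
    stop("ani_threshold must lie in [0, 100]", call. = FALSE)
  structure(list(evalue_threshold = evalue_threshold,
                 family_coverage = family_coverage,
                 family_similarity = family_similarity,
                 paralog_coverage = paralog_coverage,
                 paralog_identity = paralog_identity,
                 ani_threshold = ani_threshold,
                 gc_filter_max = gc_filter_max,
                 gap_open = gap_open, gap_extend = gap_extend,
                 focal_cluster = focal_cluster,
                 retained_phenotype = retained_phenotype,
                 lost_phenotype = lost_phenotype,
                 min_retained_strains = min_retained_strains,
                 prefilter = isTRUE(prefilter),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the comparative-pangenomics pipeline on a strain panel
#'
#' Executes the full chain: all-vs-all local alignment, homology edges,
#' single-linkage families, presence matrix, focal-group core / outgroup
#' pan / specific core, flower-plot strain-specific counts, retained-vs-
#' lost phenotype comparison, within-strain paralog calls and copy-
#' number classification of the lost families. The run is fully
#' deterministic under a fixed configuration.
#'
#' @param panel A [strain_panel()].
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, every artifact is
#'   written as TSV together with a manifest of thresholds, seeds and
#'   stage record counts.
#' @return Object of class `pangenome_run` with elements `hits`,
#'   `edges`, `families`, `presence`, `core_focal`, `pan_others`,
#'   `specific_core`, `strain_unique`, `lost`, `paralog_calls`,
#'   `copy_class`, `config` and `manifest`.
#' @export
run_pipeline <- function(panel, config = pipeline_config(),
                         output_dir = NULL) {
  if (!inherits(panel, "strain_panel"))
    stop("run_pipeline: panel must be a strain_panel", call. = FALSE)
  loci <- panel_loci(panel)
  if (nrow(loci) == 0L)
    stop("run_pipeline: the panel contains no proteins", call. = FALSE)
  md <- panel$metadata
  params <- alignment_params(gap_open = config$gap_open,
                             gap_extend = config$gap_extend,
                             evalue_threshold = config$evalue_threshold)
  lengths <- setNames(loci$length, loci$locus_id)
  strain_of <- setNames(loci$strain_id, loci$locus_id)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  hits <- stage("align",
                all_vs_all_hits(panel, params = params,
                                prefilter = config$prefilter))
  edges <- stage("edges",
                 homology_edges(hits, lengths,
                                coverage_min = config$family_coverage,
                                similarity_min = config$family_similarity))
  families <- stage("families",
                    build_families(edges, loci[, c("strain_id", "locus_id")]))
  pm <- stage("presence", presence_matrix(families, md))

  focal <- strains_by(md, cluster = config$focal_cluster)
  others <- setdiff(md$strain_id, focal)
  if (length(focal) == 0L)
    stop("no strains carry the focal cluster label '",
         config$focal_cluster, "'", call. = FALSE)
  core_focal <- stage("core", core_families(pm, focal))
  pan_others <- if (length(others)) stage("pan", pan_families(pm, others))
                else character(0)
  spec_core <- stage("specific_core", specific_core(pm, focal, others))
  petals <- stage("flower", strain_unique_counts(pm))

  retained <- strains_by(md, phenotype = config$retained_phenotype)
  lost_grp <- strains_by(md, phenotype = config$lost_phenotype)
  min_ret <- if (is.null(config$min_retained_strains)) length(retained)
             else config$min_retained_strains
  lost <- if (length(retained) && length(lost_grp))
    stage("lost", lost_families(pm, retained, lost_grp,
                                min_retained_strains = min_ret))
  else character(0)

  para_pairs <- stage("paralogs",
                      paralog_pairs_from_hits(
                        hits, lengths, strain_of,
                        coverage_min = config$paralog_coverage,
                        identity_min = config$paralog_identity))
  calls <- split(para_pairs$paralog, para_pairs$locus)
  all_calls <- setNames(vector("list", nrow(loci)), loci$locus_id)
  all_calls[names(calls)] <- calls
  all_calls[setdiff(loci$locus_id, names(calls))] <-
    list(character(0))
  copy_class <- if (length(lost))
    stage("copy_number",
          classify_copy_number(lost, families, all_calls, retained))
  else setNames(character(0), character(0))

  manifest <- c(
    lapply(config[c("evalue_threshold", "family_coverage",
                    "family_similarity", "paralog_coverage",
                    "paralog_identity", "ani_threshold", "gc_filter_max",
                    "gap_open", "gap_extend", "focal_cluster",
                    "retained_phenotype", "lost_phenotype", "seed")],
           as.character),
    list(n_strains = as.character(nrow(md)),
         n_proteins = as.character(nrow(loci)),
         n_hits = as.character(nrow(hits)),
         n_edges = as.character(nrow(edges)),
         n_families = as.character(nrow(pm)),
         n_core_focal = as.character(length(core_focal)),
         n_specific_core = as.character(length(spec_core)),
         n_lost = as.character(length(lost)),
         n_paralog_calls = as.character(nrow(para_pairs))))

  run <- structure(list(hits = hits, edges = edges, families = families,
                        presence = pm, core_focal = core_focal,
                        pan_others = pan_others, specific_core = spec_core,
                        strain_unique = petals, lost = lost,
                        paralog_calls = all_calls, copy_class = copy_class,
                        config = config, manifest = manifest),
                   class = "pangenome_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(run$families, "families.tsv")
  pm <- run$presence
  w(cbind(family_id = rownames(pm), as.data.frame(pm)), "presence_matrix.tsv")
  w(data.frame(strain_id = names(run$strain_unique),
               n_specific = unname(run$strain_unique)), "flower_counts.tsv")
  w(data.frame(set = c("core_focal", "pan_others", "specific_core", "lost"),
               size = c(length(run$core_focal), length(run$pan_others),
                        length(run$specific_core), length(run$lost))),
    "venn_summary.tsv")
  w(data.frame(family_id = run$lost,
               copy_class = unname(run$copy_class[run$lost])),
    "lost_families.tsv")
  para <- data.frame(
    locus = rep(names(run$paralog_calls),
                lengths(run$paralog_calls)),
    paralog = unlist(run$paralog_calls, use.names = FALSE))
  w(para, "paralog_pairs.tsv")
  writeLines(paste(names(run$manifest), unlist(run$manifest), sep = "\t"),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @export
print.pangenome_run <- function(x, ...) {
  cat("pangenome_run\n")
  cat("  strains:        ", x$manifest$n_strains, "\n")
  cat("  proteins:       ", x$manifest$n_proteins, "\n")
  cat("  families:       ", x$manifest$n_families, "\n")
  cat("  focal core:     ", length(x$core_focal), "\n")
  cat("  specific core:  ", length(x$specific_core), "\n")
  cat("  lost families:  ", length(x$lost), "\n")
  invisible(x)
}

#' @method summary pangenome_run
#' @export
summary.pangenome_run <- function(object, ...) {
  cc <- table(factor(object$copy_class,
                     levels = c("several_copies", "single_copy")))
  out <- list(
    n_strains = as.integer(object$manifest$n_strains),
    n_proteins = as.integer(object$manifest$n_proteins),
    n_families = as.integer(object$manifest$n_families),
    core_focal = length(object$core_focal),
    specific_core = length(object$specific_core),
    lost = length(object$lost),
    lost_several_copies = as.integer(cc[["several_copies"]]),
    lost_single_copy = as.integer(cc[["single_copy"]]),
    strain_unique = object$strain_unique)
  class(out) <- "summary.pangenome_run"
  out
}

#' @export
print.summary.pangenome_run <- function(x, ...) {
  cat("Comparative pangenome summary\n")
  cat(sprintf("  %d strains, %d proteins, %d families\n",
              x$n_strains, x$n_proteins, x$n_families))
  cat(sprintf("  focal core %d | specific core %d | lost %d (%d with paralogs, %d single-copy)\n",
              x$core_focal, x$specific_core, x$lost,
              x$lost_several_copies, x$lost_single_copy))
  cat("  strain-specific families:",
      paste(sprintf("%s=%d", names(x$strain_unique), x$strain_unique),
            collapse = " "), "\n")
  invisible(x)
}
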