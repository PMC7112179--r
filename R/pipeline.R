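# End-to-end orchestration over a single artifact directory with stable
# file names, so downstream commands find the outputs of upstream ones and
# tests can diff artifacts. Every command writes a manifest recording the
# exact configuration and seed that produced the artifacts; re-running
# from the same configuration reproduces them byte for byte.

#' Pipeline configuration
#'
#' All thresholds default to the values used throughout the analyses:
#' 2 kb proximity, minimum summed TE count 10, significance 0.05, top 20%
#' expression quantile, top 20,000 features in bins of 200, very-high
#' expression at log2(FPKM) = 8, seedling reference tissue.
#'
#' @param proximity_bp,min_total,alpha,top_quantile,n_top,bin_size,high_log2fpkm
#'   analysis thresholds (see Details).
#' @param reference_tissue reference for differential expression.
#' @param class_tissues named character vector mapping the roles `mp`,
#'   `sc`, `seedling` to tissue labels for gene-class assignment.
#' @param seed integer seed used by `simulate`.
#' @param sim named list of overrides passed to [sim_config()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(proximity_bp = 2000L, min_total = 10L,
                            alpha = 0.05, top_quantile = 0.20,
                            n_top = 20000L, bin_size = 200L,
                            high_log2fpkm = 8, reference_tissue = "seedling",
                            class_tissues = c(mp = "pollen",
                                              sc = "sperm_cell",
                                              seedling = "seedling"),
                            seed = 1L, sim = list()) {
  structure(as.list(environment()), class = "pipeline_config")
}

artifact_path <- function(out_dir, name) file.path(out_dir, name)

write_manifest <- function(out_dir, command, config, seed) {
  cfg_file <- tempfile()
  saveRDS(config, cfg_file)
  manifest <- list(
    command = command, seed = seed,
    package_version = as.character(utils::packageVersion("pollenTE")),
    config_md5 = unname(tools::md5sum(cfg_file)),
    config = unclass(config))
  unlink(cfg_file)
  jsonlite::write_json(manifest,
                       artifact_path(out_dir, paste0("manifest_", command,
                                                     ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

load_sim_annotation <- function(out_dir) {
  read_annotation_gff3(
    artifact_path(out_dir, "genes.gff3"),
    artifact_path(out_dir, "tes.gff3"),
    artifact_path(out_dir, "centromeres.tsv"))
}

#' Run one pipeline command
#'
#' Commands:
#' * `simulate` -- generate annotation (GFF3), counts, ear counts and
#'   phenotype tables into `out_dir`, with truth tables.
#' * `te-classify` -- proximity partition, per-tissue differential
#'   expression of distal TEs against the reference, four-way TE
#'   categories, family enrichment of the dynamic set.
#' * `diffexpr` -- write the per-tissue TE differential-expression tables.
#' * `coexpress` -- gene FPKM ranking, binned nearby-TE counts and Kendall
#'   association per activated tissue.
#' * `classify-genes` -- FPKM-based expression classes.
#' * `transmission` -- QC, per-allele quasi-binomial tests, class
#'   comparisons and expression-fitness regressions.
#' * `phenotype` -- fertilization-outcome and seed-census statistics.
#' * `report` -- collate the result tables into `report.tsv`.
#'
#' @param command one of the labels above.
#' @param out_dir artifact directory (created if needed).
#' @param config a [pipeline_config()].
#' @param seed overrides `config$seed` when given.
#' @return Invisibly, a named list of the artifacts written.
#' @export
run_pipeline <- function(command = c("simulate", "te-classify", "diffexpr",
                                     "coexpress", "classify-genes",
                                     "transmission", "phenotype", "report"),
                         out_dir, config = pipeline_config(), seed = NULL) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arts <- switch(command,
    simulate = pipe_simulate(out_dir, config, seed),
    `te-classify` = pipe_te_classify(out_dir, config),
    diffexpr = pipe_diffexpr(out_dir, config),
    coexpress = pipe_coexpress(out_dir, config),
    `classify-genes` = pipe_classify_genes(out_dir, config),
    transmission = pipe_transmission(out_dir, config),
    phenotype = pipe_phenotype(out_dir, config),
    report = pipe_report(out_dir, config))
  write_manifest(out_dir, command, config, seed)
  invisible(arts)
}

pipe_simulate <- function(out_dir, config, seed) {
  scfg <- do.call(sim_config, c(list(seed = seed), config$sim))
  ann <- gen_annotation(scfg)
  write_annotation_gff3(ann, artifact_path(out_dir, "genes.gff3"),
                        artifact_path(out_dir, "tes.gff3"),
                        artifact_path(out_dir, "centromeres.tsv"))
  gc <- gen_counts(scfg, ann)
  write_counts_tsv(gc$counts, artifact_path(out_dir, "counts.tsv"))
  write_tsv(gc$truth$activated,
            artifact_path(out_dir, "truth_activated.tsv"))
  write_tsv(gc$truth$gene_preferred,
            artifact_path(out_dir, "truth_gene_preferred.tsv"))
  ears <- gen_ear_counts(scfg)
  write_ear_tsv(ears, artifact_path(out_dir, "ears.tsv"))
  ph <- gen_phenotypes(scfg)
  write_tsv(ph$fertilization, artifact_path(out_dir, "fertilization.tsv"))
  write_tsv(ph$census, artifact_path(out_dir, "seed_census.tsv"))
  list(annotation = ann, counts = gc$counts)
}

te_de_by_tissue <- function(out_dir, config) {
  ann <- load_sim_annotation(out_dir)
  cm <- read_counts_tsv(artifact_path(out_dir, "counts.tsv"))
  prox <- classify_proximity(ann, config$proximity_bp)
  distal <- names(prox$te_category)[prox$te_category == "distal"]
  te_cm <- count_matrix(
    cm$values[intersect(rownames(cm$values), distal), , drop = FALSE],
    cm$samples)
  tissues <- setdiff(unique(cm$samples$tissue), config$reference_tissue)
  de <- lapply(tissues, function(t)
    nb_differential(te_cm, config$reference_tissue, t,
                    alpha = config$alpha))
  names(de) <- tissues
  list(annotation = ann, counts = cm, proximity = prox, de = de)
}

pipe_te_classify <- function(out_dir, config) {
  ctx <- te_de_by_tissue(out_dir, config)
  cats <- categorize_tes(ctx$annotation, ctx$counts, ctx$de,
                         min_total = config$min_total,
                         alpha = config$alpha, proximity = ctx$proximity)
  write_tsv(cats, artifact_path(out_dir, "te_categories.tsv"))
  write_category_bed6(ctx$annotation,
                      stats::setNames(cats$category, cats$te_id),
                      artifact_path(out_dir, "te_categories.bed"))
  dyn <- ctx$annotation$tes[
    ctx$annotation$tes$te_id %in% cats$te_id[cats$category == "dynamic"], ]
  fe <- family_enrichment(dyn, ctx$annotation$tes)
  write_tsv(fe, artifact_path(out_dir, "family_enrichment_dynamic.tsv"))
  list(categories = cats, family_enrichment = fe)
}

pipe_diffexpr <- function(out_dir, config) {
  ctx <- te_de_by_tissue(out_dir, config)
  for (t in names(ctx$de))
    write_tsv(ctx$de[[t]],
              artifact_path(out_dir, paste0("de_te_", t, ".tsv")))
  ctx$de
}

gene_fpkm_matrix <- function(ann, cm) {
  lens <- stats::setNames(ann$transcripts$transcript_length_bp,
                          ann$transcripts$gene_id)
  gene_ids <- intersect(rownames(cm$values), names(lens))
  fpkm_matrix(count_matrix(cm$values[gene_ids, , drop = FALSE],
                           cm$samples), lens)
}

pipe_coexpress <- function(out_dir, config) {
  ctx <- te_de_by_tissue(out_dir, config)
  em <- gene_fpkm_matrix(ctx$annotation, ctx$counts)
  out <- list()
  assoc_all <- NULL
  for (t in names(ctx$de)) {
    prof <- bin_and_count(
      em, t, ctx$de[[t]], ctx$proximity$gene_te_map,
      n_top = min(config$n_top, nrow(em$values)),
      bin_size = config$bin_size)
    write_tsv(as.data.frame(prof),
              artifact_path(out_dir, paste0("bin_profile_", t, ".tsv")))
    assoc <- bin_association(prof)
    assoc_all <- rbind(assoc_all, assoc)
    out[[t]] <- list(profile = prof, association = assoc)
  }
  write_tsv(assoc_all, artifact_path(out_dir, "bin_association.tsv"))
  out
}

pipe_classify_genes <- function(out_dir, config) {
  ann <- load_sim_annotation(out_dir)
  cm <- read_counts_tsv(artifact_path(out_dir, "counts.tsv"))
  em <- gene_fpkm_matrix(ann, cm)
  cls <- assign_classes(em, quantile = config$top_quantile,
                        high_threshold_log2 = config$high_log2fpkm,
                        tissues = config$class_tissues)
  write_tsv(cls, artifact_path(out_dir, "gene_classes.tsv"))
  cls
}

pipe_transmission <- function(out_dir, config) {
  ears <- read_ear_tsv(artifact_path(out_dir, "ears.tsv"))
  qc <- qc_ears(ears)
  write_tsv(qc$report, artifact_path(out_dir, "transmission_qc.tsv"))
  res <- test_all_alleles(qc$ears, alpha = config$alpha)
  write_tsv(as.data.frame(res), artifact_path(out_dir, "transmission.tsv"))
  cmp <- class_defect_comparison(res,
                                 split_log2fpkm = config$high_log2fpkm)
  cmp_df <- do.call(rbind, lapply(cmp, function(x)
    data.frame(comparison = x$comparison, p_value = x$test$p_value)))
  write_tsv(cmp_df, artifact_path(out_dir, "class_comparisons.tsv"))
  reg <- tryCatch(expression_fitness_regression(res),
                  error = function(e) NULL)
  if (!is.null(reg))
    write_tsv(data.frame(
      response = c("transmission_rate", "neg_log10_p"),
      slope = c(reg[[1]]$slope, reg[[2]]$slope),
      slope_p = c(reg[[1]]$slope_p, reg[[2]]$slope_p),
      r2_adjusted = c(reg[[1]]$r2_adjusted, reg[[2]]$r2_adjusted)),
      artifact_path(out_dir, "expression_fitness_regression.tsv"))
  list(results = res, comparisons = cmp, regressions = reg)
}

pipe_phenotype <- function(out_dir, config) {
  fert <- read_tsv(artifact_path(out_dir, "fertilization.tsv"))
  census <- read_tsv(artifact_path(out_dir, "seed_census.tsv"))
  groups <- fert$group
  fo <- fertilization_outcome_test(fert, groups[2], groups[1])
  write_tsv(cbind(fo$classification,
                  fisher_p = c(fo$test$p_value, NA)),
            artifact_path(out_dir, "fertilization_test.tsv"))
  cg <- unique(census$genotype_group)
  ct <- census_tests(census,
                     treatment_groups = grep("mutant", cg, value = TRUE),
                     control_groups = grep("control", cg, value = TRUE))
  write_tsv(ct, artifact_path(out_dir, "census_tests.tsv"))
  list(fertilization = fo, census = ct)
}

pipe_report <- function(out_dir, config) {
  files <- c("te_categories.tsv", "bin_association.tsv",
             "gene_classes.tsv", "transmission.tsv",
             "class_comparisons.tsv", "fertilization_test.tsv",
             "census_tests.tsv")
  rows <- list()
  for (f in files) {
    p <- artifact_path(out_dir, f)
    if (!file.exists(p)) next
    df <- read_tsv(p)
    rows[[f]] <- data.frame(artifact = f, n_rows = nrow(df))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  write_tsv(report, artifact_path(out_dir, "report.tsv"))
  report
}
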