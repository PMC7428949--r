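#' Pipeline configuration
#'
#' Bundles every stage's parameters plus input/output paths.  Input paths
#' may be omitted when the corresponding objects are passed to
#' [run_pipeline()] directly.
#'
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param counts_path,metadata_path Count matrix and sample metadata TSVs.
#' @param drugs_up_path,drugs_down_path Paired GMT drug-signature files.
#' @param collection_path GMT pathway collection for enrichment.
#' @param thresholds A [de_thresholds()].
#' @param network A [network_config()] (used for both groups).
#' @param edge_filter List with `min_abs_r` and `max_p` for
#'   [export_group_networks()].
#' @param drug_p_max,drug_cov_min Drug ranking filters.
#' @param qc List with `n_pcs`, `mad_k` (PCA screen) and `cut_height`
#'   (dendrogram screen; `NULL` for automatic).
#' @param diffcorr_genes Gene subset for differential correlation; `NULL`
#'   selects the largest normal-group module (capped at 200 genes).
#' @param disease_tier Threshold tier of the disease signature used for
#'   drug matching (`"loose"` by default).
#' @param enrich_p_max Raw-p significance threshold for enrichment.
#' @param seed Seed recorded in the manifest (the stages themselves are
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            counts_path = NULL, metadata_path = NULL,
                            drugs_up_path = NULL, drugs_down_path = NULL,
                            collection_path = NULL,
                            thresholds = de_thresholds(),
                            network = network_config(),
                            edge_filter = list(min_abs_r = 0.3, max_p = 0.05),
                            drug_p_max = 1e-5, drug_cov_min = 0.95,
                            qc = list(n_pcs = NULL, mad_k = 8,
                                      cut_height = NULL),
                            diffcorr_genes = NULL,
                            disease_tier = c("loose", "strict"),
                            enrich_p_max = 0.001,
                            seed = 1) {
  structure(list(out_dir = out_dir, counts_path = counts_path,
                 metadata_path = metadata_path,
                 drugs_up_path = drugs_up_path,
                 drugs_down_path = drugs_down_path,
                 collection_path = collection_path,
                 thresholds = thresholds, network = network,
                 edge_filter = edge_filter, drug_p_max = drug_p_max,
                 drug_cov_min = drug_cov_min, qc = qc,
                 diffcorr_genes = diffcorr_genes,
                 disease_tier = match.arg(disease_tier),
                 enrich_p_max = enrich_p_max, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full multilevel expression-change pipeline
#'
#' Executes, in order: PCA sample QC, negative-binomial differential
#' expression with both threshold tiers, per-group dendrogram QC and
#' coexpression module detection, the module overlap cross-tab, pairwise
#' differential correlation on a selected gene subset with per-group edge
#' lists, optional pathway enrichment of the strict DE set, and optional
#' drug-signature reversal ranking.  Each stage writes a TSV under
#' `config$out_dir` and a JSON manifest records the parameters, seed,
#' input hashes and row counts (no timestamps, so repeated runs on
#' identical inputs produce identical manifests).
#'
#' @param config A [pipeline_config()].
#' @param cm A [count_matrix()]; if `NULL`, read from the config paths.
#' @param drug_library A [signature_library()]; if `NULL`, read from the
#'   config paths when given, else the drug stage is skipped.
#' @param collection Named list of gene sets; if `NULL`, read from
#'   `collection_path` when given, else enrichment is skipped.
#' @return Invisibly, a list with every stage result (`qc_pca`, `de`,
#'   `signature`, `qc_dendro`, `modules`, `overlap`, `diffcorr`,
#'   `networks`, `enrichment`, `drugs`) plus the `manifest`.
#' @export
run_pipeline <- function(config, cm = NULL, drug_library = NULL,
                         collection = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cm)) {
    for (p in c(config$counts_path, config$metadata_path))
      if (is.null(p) || !file.exists(p))
        stop("input path missing or not found: ",
             if (is.null(p)) "(not set)" else p)
    cm <- read_counts(config$counts_path, config$metadata_path)
  }
  if (is.null(drug_library) && !is.null(config$drugs_up_path))
    drug_library <- read_signatures_gmt(config$drugs_up_path,
                                        config$drugs_down_path)
  if (is.null(collection) && !is.null(config$collection_path))
    collection <- read_gmt(config$collection_path)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  res <- list()

  ## stage: PCA QC, then DE on kept samples
  res$qc_pca <- pca_outliers(cm, config$qc$n_pcs, config$qc$mad_k)
  files["qc_pca"] <- write_tsv(res$qc_pca$scores, out("qc_pca.tsv"))
  cm_qc <- apply_qc(cm, res$qc_pca)

  res$de <- de_test(cm_qc)
  files["de"] <- write_tsv(res$de, out("de_results.tsv"))
  loose <- apply_thresholds(res$de, config$thresholds, "loose")
  strict <- apply_thresholds(res$de, config$thresholds, "strict")
  sig_sets <- apply_thresholds(res$de, config$thresholds,
                               config$disease_tier)
  res$signature <- disease_signature(sig_sets$up, sig_sets$down,
                                     res$de$gene_id,
                                     tier = config$disease_tier)
  files["de_sets"] <- write_tsv(
    data.frame(tier = rep(c("loose", "loose", "strict", "strict"),
                          c(length(loose$up), length(loose$down),
                            length(strict$up), length(strict$down))),
               direction = c(rep("up", length(loose$up)),
                             rep("down", length(loose$down)),
                             rep("up", length(strict$up)),
                             rep("down", length(strict$down))),
               gene_id = c(loose$up, loose$down, strict$up, strict$down)),
    out("de_gene_sets.tsv"))

  ## stage: per-group dendrogram QC + modules
  expr_group <- list(); res$modules <- list(); res$qc_dendro <- list()
  for (g in levels(cm_qc$groups)) {
    cm_g <- subset_counts(cm_qc,
                          samples = names(cm_qc$groups)[cm_qc$groups == g])
    keep <- rowSums(cm_g$counts) > 0
    cm_g <- subset_counts(cm_g, genes = rownames(cm_g$counts)[keep])
    res$qc_dendro[[g]] <- dendrogram_outliers(cm_g, config$qc$cut_height)
    cm_g <- apply_qc(cm_g, res$qc_dendro[[g]])
    expr_group[[g]] <- normalized_log2(cm_g)
    res$modules[[g]] <- detect_modules(expr_group[[g]], config$network,
                                       group = g)
    files[paste0("modules_", g)] <- write_tsv(
      data.frame(gene_id = names(res$modules[[g]]$modules),
                 group = g, module = unname(res$modules[[g]]$modules)),
      out(paste0("modules_", g, ".tsv")))
    if (!is.null(res$modules[[g]]$eigengenes))
      files[paste0("eigengenes_", g)] <- write_tsv(
        data.frame(sample_id = rownames(res$modules[[g]]$eigengenes),
                   res$modules[[g]]$eigengenes, check.names = FALSE),
        out(paste0("eigengenes_", g, ".tsv")))
  }
  gl <- levels(cm_qc$groups)
  res$overlap <- module_overlap_table(res$modules[[gl[1]]],
                                      res$modules[[gl[2]]])
  files["overlap"] <- write_tsv(res$overlap, out("module_overlap.tsv"))

  ## stage: differential correlation on the selected subset
  subset <- config$diffcorr_genes
  if (is.null(subset)) {
    mods <- res$modules[[gl[1]]]$modules
    non_grey <- mods[mods != "grey"]
    if (length(non_grey) > 0) {
      biggest <- names(which.max(table(non_grey)))
      subset <- utils::head(names(non_grey)[non_grey == biggest], 200)
    }
  }
  subset <- intersect(subset,
                      intersect(rownames(expr_group[[gl[1]]]),
                                rownames(expr_group[[gl[2]]])))
  if (length(subset) >= 2) {
    res$diffcorr <- diffcorr(expr_group[[gl[1]]], expr_group[[gl[2]]],
                             subset)
    files["diffcorr"] <- write_tsv(res$diffcorr, out("diffcorr.tsv"))
    res$networks <- export_group_networks(res$diffcorr,
                                          config$edge_filter$min_abs_r,
                                          config$edge_filter$max_p)
    for (g in names(res$networks))
      files[paste0("network_", g)] <-
        write_tsv(res$networks[[g]], out(paste0("network_", g, ".tsv")))
  }

  ## stage: enrichment of the strict DE set
  if (!is.null(collection)) {
    res$enrichment <- ora(c(strict$up, strict$down), collection,
                          universe = res$de$gene_id,
                          p_max = config$enrich_p_max)
    files["enrichment"] <- write_tsv(res$enrichment, out("enrichment.tsv"))
  }

  ## stage: drug reversal ranking
  if (!is.null(drug_library)) {
    res$drugs <- rank_drugs(res$signature, drug_library,
                            p_max = config$drug_p_max,
                            cov_min = config$drug_cov_min)
    files["drugs"] <- write_tsv(res$drugs, out("drug_ranking.tsv"))
  }

  input_paths <- unlist(config[c("counts_path", "metadata_path",
                                 "drugs_up_path", "drugs_down_path",
                                 "collection_path")])
  input_paths <- input_paths[!vapply(input_paths, is.null, TRUE)]
  manifest <- list(
    seed = config$seed,
    parameters = list(thresholds = unclass(config$thresholds),
                      network = unclass(config$network),
                      edge_filter = config$edge_filter,
                      drug_p_max = config$drug_p_max,
                      drug_cov_min = config$drug_cov_min,
                      qc = config$qc,
                      disease_tier = config$disease_tier,
                      enrich_p_max = config$enrich_p_max),
    input_hashes = if (length(input_paths) > 0)
      as.list(tools::md5sum(unlist(input_paths))) else list(),
    samples_removed_pca = res$qc_pca$removed_sample_ids,
    n_de_tested = nrow(res$de),
    n_de_loose = length(loose$up) + length(loose$down),
    n_de_strict = length(strict$up) + length(strict$down),
    n_modules = lapply(res$modules, function(m)
      length(setdiff(unique(m$modules), "grey"))),
    repurpose = if (!is.null(res$drugs)) list(
      n_drugs = nrow(res$drugs),
      n_passing = sum(!is.na(res$drugs$rank)),
      top_passing = if (any(!is.na(res$drugs$rank)))
        res$drugs$drug_id[which(res$drugs$rank == 1)] else NULL),
    outputs = as.list(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
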