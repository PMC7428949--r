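#!/usr/bin/env Rscript

# Thin command-line wrapper over sigreverse::run_pipeline().
#
#   Rscript scripts/run_pipeline.R --counts counts.tsv --metadata meta.tsv \
#     --out-dir results [--drugs-up up.gmt --drugs-down down.gmt] \
#     [--collection sets.gmt] [--qc-npcs 2] [--qc-madk 5] \
#     [--qc-cut-height H] [--soft-power 6] [--p-max 1e-5] [--cov-min 0.95] \
#     [--seed 1]

suppressPackageStartupMessages({
  library(optparse)
  library(sigreverse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--counts", type = "character"),
  make_option("--metadata", type = "character"),
  make_option("--out-dir", type = "character", dest = "out_dir"),
  make_option("--drugs-up", type = "character", dest = "drugs_up",
              default = NULL),
  make_option("--drugs-down", type = "character", dest = "drugs_down",
              default = NULL),
  make_option("--collection", type = "character", default = NULL),
  make_option("--qc-npcs", type = "integer", dest = "qc_npcs",
              default = NA),
  make_option("--qc-madk", type = "double", dest = "qc_madk", default = 8),
  make_option("--qc-cut-height", type = "double", dest = "qc_cut",
              default = NA),
  make_option("--soft-power", type = "integer", dest = "soft_power",
              default = 6),
  make_option("--p-max", type = "double", dest = "p_max", default = 1e-5),
  make_option("--cov-min", type = "double", dest = "cov_min",
              default = 0.95),
  make_option("--disease-sig-tier", type = "character", dest = "tier",
              default = "loose"),
  make_option("--seed", type = "integer", default = 1))))

config <- pipeline_config(
  out_dir = opts$out_dir,
  counts_path = opts$counts, metadata_path = opts$metadata,
  drugs_up_path = opts$drugs_up, drugs_down_path = opts$drugs_down,
  collection_path = opts$collection,
  network = network_config(soft_power = opts$soft_power),
  drug_p_max = opts$p_max, drug_cov_min = opts$cov_min,
  qc = list(n_pcs = if (is.na(opts$qc_npcs)) NULL else opts$qc_npcs,
            mad_k = opts$qc_madk,
            cut_height = if (is.na(opts$qc_cut)) NULL else opts$qc_cut),
  disease_tier = opts$tier,
  seed = opts$seed)

res <- run_pipeline(config)
m <- res$manifest
cat("samples removed (PCA):",
    paste(unlist(m$samples_removed_pca), collapse = ", "), "\n")
cat("DE genes: ", m$n_de_loose, " loose / ", m$n_de_strict, " strict\n",
    sep = "")
cat("modules:", paste(names(m$n_modules), unlist(m$n_modules),
                      sep = "=", collapse = ", "), "\n")
if (!is.null(m$repurpose))
  cat("drugs passing filters: ", m$repurpose$n_passing,
      if (m$repurpose$n_passing > 0)
        paste0(" (top: ", m$repurpose$top_passing, ")") else "", "\n",
      sep = "")
cat("outputs in", config$out_dir, "\n")
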