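#' Specify one planted coexpression module
#'
#' @param size Number of genes in the module.
#' @param r Target within-module Pearson correlation (0 < r < 1) of
#'   log2-normalised expression.
#' @param disrupted If `TRUE` the module's latent factor is silenced in the
#'   cancer group, so the coexpression exists in normal samples only.
#' @return A list describing the module.
#' @export
module_spec <- function(size, r, disrupted = FALSE) {
  stopifnot(size >= 3, r > 0, r < 1, is.logical(disrupted))
  list(size = as.integer(size), r = r, disrupted = isTRUE(disrupted))
}

#' Configuration of the synthetic-data generator
#'
#' Defaults define the study conditions used throughout the package's
#' tests: a 2,000-gene universe, 50 normal + 50 cancer samples, 10% of
#' genes differentially expressed at |log2FC| = 2 (100 up + 100 down), five
#' planted coexpression modules of 100 genes at within-module r = 0.6 (one
#' disrupted in the cancer group), 2 outlier samples, and a drug library of
#' 200 random signatures of 50 genes per direction plus one planted
#' reversal drug.
#'
#' @param n_genes Number of genes.
#' @param n_normal,n_cancer Samples per group (either may be 0; downstream
#'   stages impose their own minima).
#' @param seed Integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @param de_fraction Fraction of genes differentially expressed, in [0, 1).
#' @param lfc_magnitude Absolute log2 fold-change planted in DE genes.
#' @param module_spec List of [module_spec()] entries.
#' @param dispersion_params Numeric `c(a0, a1)` of the NB dispersion trend
#'   alpha(mu) = a0 + a1/mu.
#' @param mean_log_params Numeric `c(location, scale)` of the normal
#'   distribution of per-gene log2 base means.
#' @param n_outlier_samples Number of samples given an aberrant profile
#'   (per-gene log2 shifts with mean +2) and doubled library size.
#' @param library_size_range Multiplicative range `c(lo, hi)` from which
#'   per-sample size factors are drawn log-uniformly.
#' @param n_drug_signatures Number of random drug signatures.
#' @param drug_signature_size Genes per direction in each drug signature.
#' @param planted_reversal_drug If `TRUE`, one extra drug whose signature
#'   exactly reverses the planted disease signature is added to the library.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_normal = 50,
                              n_cancer = 50,
                              seed = 1,
                              de_fraction = 0.1,
                              lfc_magnitude = 2,
                              module_spec = default_module_spec(),
                              dispersion_params = c(a0 = 0.01, a1 = 1.5),
                              mean_log_params = c(location = 5, scale = 2),
                              n_outlier_samples = 2,
                              library_size_range = c(0.5, 2),
                              n_drug_signatures = 200,
                              drug_signature_size = 50,
                              planted_reversal_drug = TRUE) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_normal = as.integer(n_normal),
              n_cancer = as.integer(n_cancer),
              seed = as.integer(seed),
              de_fraction = de_fraction,
              lfc_magnitude = lfc_magnitude,
              module_spec = module_spec,
              dispersion_params = unname(dispersion_params),
              mean_log_params = unname(mean_log_params),
              n_outlier_samples = as.integer(n_outlier_samples),
              library_size_range = library_size_range,
              n_drug_signatures = as.integer(n_drug_signatures),
              drug_signature_size = as.integer(drug_signature_size),
              planted_reversal_drug = isTRUE(planted_reversal_drug))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_module_spec <- function() {
  c(replicate(4, module_spec(100, 0.6), simplify = FALSE),
    list(module_spec(100, 0.6, disrupted = TRUE)))
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1) stop("n_genes must be positive")
    if (n_normal < 0 || n_cancer < 0 || n_normal + n_cancer < 1)
      stop("sample counts must be non-negative with at least one sample")
    if (de_fraction < 0 || de_fraction >= 1)
      stop("de_fraction must lie in [0, 1)")
    if (lfc_magnitude < 0) stop("lfc_magnitude must be non-negative")
    msizes <- vapply(module_spec, `[[`, 1L, "size")
    n_de <- round(de_fraction * n_genes)
    if (n_de + sum(msizes) > n_genes)
      stop("planted DE genes plus module sizes exceed n_genes")
    if (any(dispersion_params < 0) || sum(dispersion_params) <= 0)
      stop("dispersion_params must be non-negative, not both zero")
    if (mean_log_params[2] < 0) stop("mean_log scale must be non-negative")
    if (n_outlier_samples < 0 || n_outlier_samples > n_normal + n_cancer)
      stop("n_outlier_samples out of range")
    if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
        diff(library_size_range) < 0)
      stop("library_size_range must be positive c(lo, hi) with lo <= hi")
    if (n_drug_signatures < 0 || drug_signature_size < 1)
      stop("drug library sizes must be positive")
  })
  invisible(cfg)
}

# log2-scale variance of log(count) induced by NB sampling around mean mu
# with dispersion alpha (delta method: var(log K) ~ 1/mu + alpha).
nb_log2_noise_var <- function(mu, alpha) (1 / mu + alpha) / log(2)^2

#' Simulate a count matrix with planted structure
#'
#' Counts are negative-binomial (gamma-Poisson) around a per-gene,
#' per-sample mean `s_j * 2^eta_gj` where `eta_gj` sums a log-normal gene
#' base mean, a group effect of +/- `lfc_magnitude` for planted DE genes, a
#' per-module latent factor scaled so the within-module Pearson correlation
#' of log2 expression hits the module's target (the loading solves
#' r = lambda^2 / (lambda^2 + sigma^2) against the NB log-scale noise
#' variance), and, for outlier samples, an aberrant per-gene profile shift.
#' Dispersion follows the trend alpha(mu) = a0 + a1/mu.  Disrupted modules
#' have their factor loading set to zero in the cancer group.  Module genes'
#' base means are floored at 50 counts so the loading calibration (a
#' continuous approximation) holds.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `cm` (a [count_matrix()]) and `truth`, a
#'   list recording every planted structure: `de_genes` (named vector of
#'   signed true log2 fold-changes), `module_membership` (named character
#'   vector, planted module per gene), `disrupted_modules`,
#'   `reversal_drug_id` (or `NULL`), `outlier_sample_ids`, and the per-gene
#'   `true_dispersion`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  n <- config$n_normal + config$n_cancer
  gene_ids <- sprintf("g%05d", seq_len(G))
  sample_ids <- c(sprintf("N%03d", seq_len(config$n_normal)),
                  sprintf("C%03d", seq_len(config$n_cancer)))
  groups <- stats::setNames(rep(c("normal", "cancer"),
                                c(config$n_normal, config$n_cancer)),
                            sample_ids)
  is_cancer <- groups == "cancer"

  ## gene blocks: [DE][module 1..M][background]
  n_de <- round(config$de_fraction * G)
  n_up <- ceiling(n_de / 2)
  de_idx <- seq_len(n_de)
  de_sign <- rep(c(1, -1), c(n_up, n_de - n_up))
  msizes <- vapply(config$module_spec, `[[`, 1L, "size")
  module_id <- rep(NA_character_, G)
  pos <- n_de
  for (m in seq_along(config$module_spec)) {
    module_id[pos + seq_len(msizes[m])] <- sprintf("M%d", m)
    pos <- pos + msizes[m]
  }

  base_log2 <- stats::rnorm(G, config$mean_log_params[1],
                            config$mean_log_params[2])
  base_log2[!is.na(module_id)] <- pmax(base_log2[!is.na(module_id)],
                                       log2(50))
  mu_base <- 2^base_log2
  a0 <- config$dispersion_params[1]; a1 <- config$dispersion_params[2]
  alpha <- a0 + a1 / mu_base

  ## per-sample size factors, outliers doubled
  lsr <- log2(config$library_size_range)
  size_fac <- 2^stats::runif(n, lsr[1], lsr[2])
  outliers <- if (config$n_outlier_samples > 0)
    sort(sample(sample_ids, config$n_outlier_samples)) else character(0)
  size_fac[match(outliers, sample_ids)] <-
    2 * size_fac[match(outliers, sample_ids)]

  ## log2 mean per gene x sample
  eta <- matrix(base_log2, nrow = G, ncol = n,
                dimnames = list(gene_ids, sample_ids))
  if (n_de > 0 && config$lfc_magnitude > 0)
    eta[de_idx, is_cancer] <- eta[de_idx, is_cancer] +
      de_sign * config$lfc_magnitude

  for (m in seq_along(config$module_spec)) {
    spec <- config$module_spec[[m]]
    gi <- which(module_id == sprintf("M%d", m))
    f <- stats::rnorm(n)
    lambda <- sqrt(spec$r / (1 - spec$r) *
                     nb_log2_noise_var(mu_base[gi], alpha[gi]))
    load_mat <- outer(lambda, f)
    if (spec$disrupted) load_mat[, is_cancer] <- 0
    eta[gi, ] <- eta[gi, ] + load_mat
  }

  if (length(outliers) > 0) {
    oi <- match(outliers, sample_ids)
    eta[, oi] <- eta[, oi] + matrix(stats::rnorm(G * length(oi), 2, 1),
                                    nrow = G)
  }

  mu <- sweep(2^eta, 2, size_fac, `*`)
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = rep(1 / alpha, n)),
                   nrow = G, dimnames = list(gene_ids, sample_ids))

  truth <- list(
    de_genes = stats::setNames(de_sign * config$lfc_magnitude,
                               gene_ids[de_idx]),
    module_membership = stats::setNames(module_id, gene_ids)[!is.na(module_id)],
    disrupted_modules = sprintf("M%d", which(vapply(config$module_spec,
                                                    `[[`, TRUE, "disrupted"))),
    reversal_drug_id = if (config$planted_reversal_drug) "drug_planted" else NULL,
    outlier_sample_ids = outliers,
    true_dispersion = stats::setNames(alpha, gene_ids),
    size_factors = stats::setNames(size_fac, sample_ids))

  list(cm = count_matrix(counts, groups), truth = truth)
}

#' Simulate a drug-signature library
#'
#' Draws `n_drug_signatures` random signatures with disjoint up/down sets
#' from the gene universe; when `planted_reversal_drug` is set, appends one
#' drug whose up set consists of the top planted down-regulated disease
#' genes and whose down set consists of the top planted up-regulated
#' disease genes — the exact sign flip of the disease signature.
#'
#' @param config The [simulation_config()] used for [simulate_counts()].
#' @param truth The `truth` element returned by [simulate_counts()].
#' @return A [signature_library()] over the simulated gene universe.
#' @export
simulate_drug_library <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  sz <- config$drug_signature_size
  if (2L * sz > config$n_genes)
    stop("drug_signature_size too large for the gene universe")
  entries <- lapply(seq_len(config$n_drug_signatures), function(i) {
    g <- sample(gene_ids, 2L * sz)
    list(up = g[seq_len(sz)], down = g[sz + seq_len(sz)],
         description = "random signature")
  })
  names(entries) <- sprintf("drug_%04d", seq_len(config$n_drug_signatures))
  if (config$planted_reversal_drug) {
    de <- truth$de_genes
    up_de <- names(de)[de > 0]
    down_de <- names(de)[de < 0]
    if (length(up_de) < sz || length(down_de) < sz)
      stop("drug_signature_size exceeds available planted DE genes ",
           "per direction")
    entries[[truth$reversal_drug_id]] <-
      list(up = down_de[order(-abs(de[down_de]))][seq_len(sz)],
           down = up_de[order(-abs(de[up_de]))][seq_len(sz)],
           description = "planted reversal signature")
  }
  signature_library(entries, universe = gene_ids)
}

#' Write a simulated dataset and its ground truth to a directory
#'
#' Emits the counts/metadata TSVs, the drug library as paired GMT files and
#' the planted truth as TSV sidecars, all re-readable by the package's own
#' readers.
#'
#' @param sim The list returned by [simulate_counts()].
#' @param lib Optional [signature_library()] from [simulate_drug_library()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, lib = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  write_counts(sim$cm, paths["counts"], paths["metadata"])
  tr <- sim$truth
  write_tsv(data.frame(gene_id = names(tr$de_genes),
                       true_log2fc = unname(tr$de_genes)),
            p <- file.path(dir, "truth_de.tsv"))
  paths["truth_de"] <- p
  write_tsv(data.frame(gene_id = names(tr$module_membership),
                       module = unname(tr$module_membership)),
            p <- file.path(dir, "truth_modules.tsv"))
  paths["truth_modules"] <- p
  write_tsv(data.frame(sample_id = tr$outlier_sample_ids),
            p <- file.path(dir, "truth_outliers.tsv"))
  paths["truth_outliers"] <- p
  if (!is.null(lib)) {
    paths["drugs_up"] <- file.path(dir, "drugs_up.gmt")
    paths["drugs_down"] <- file.path(dir, "drugs_down.gmt")
    write_signatures_gmt(lib, paths["drugs_up"], paths["drugs_down"])
  }
  invisible(paths)
}
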