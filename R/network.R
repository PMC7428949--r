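#' Weighted network construction parameters
#'
#' @param soft_power Soft-threshold exponent beta applied to correlations
#'   (default 6).
#' @param network_type `"unsigned"` (`|r|^beta`) or `"signed"`
#'   (`((1+r)/2)^beta`).
#' @param min_module_size Smallest cluster kept as a module; smaller
#'   clusters are relabelled `"grey"` (default 30).
#' @param merge_eigengene_corr Modules whose eigengenes correlate above
#'   this are merged iteratively (default 0.75).
#' @param tree_cut_quantile `NULL` (default) cuts the dendrogram at the
#'   midpoint of the largest gap between consecutive merge heights in the
#'   tree's upper half — the divide between tight within-module merges and
#'   the loose background merges above them.  A numeric value in (0, 1]
#'   cuts at that quantile of merge heights instead.
#' @return A list of class `network_config`.
#' @export
network_config <- function(soft_power = 6,
                           network_type = c("unsigned", "signed"),
                           min_module_size = 30,
                           merge_eigengene_corr = 0.75,
                           tree_cut_quantile = NULL) {
  network_type <- match.arg(network_type)
  stopifnot(soft_power >= 1, min_module_size >= 3,
            merge_eigengene_corr > 0, merge_eigengene_corr <= 1,
            is.null(tree_cut_quantile) ||
              (tree_cut_quantile > 0 && tree_cut_quantile <= 1))
  structure(list(soft_power = as.integer(soft_power),
                 network_type = network_type,
                 min_module_size = as.integer(min_module_size),
                 merge_eigengene_corr = merge_eigengene_corr,
                 tree_cut_quantile = tree_cut_quantile),
            class = "network_config")
}

## Static cut height: largest-gap rule over the upper half of the merge
## heights (or a plain quantile when one is configured).
static_cut_height <- function(heights, quantile = NULL) {
  if (!is.null(quantile))
    return(stats::quantile(heights, quantile, names = FALSE))
  h <- sort(heights)
  upper <- h[h >= stats::median(h)]
  if (length(upper) < 2) return(max(h))
  gaps <- diff(upper)
  i <- which.max(gaps)
  (upper[i] + upper[i + 1]) / 2
}

#' Soft-thresholded adjacency from expression
#'
#' @param expr Numeric matrix, genes x samples, of log2-normalised
#'   expression.
#' @param power Soft-threshold exponent.
#' @param network_type `"unsigned"` or `"signed"`.
#' @return Symmetric adjacency matrix with unit diagonal, entries in [0,1].
#' @export
adjacency_matrix <- function(expr, power = 6,
                             network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  r <- suppressWarnings(stats::cor(t(expr)))
  r[is.na(r)] <- 0
  a <- if (network_type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Scale-free-fit diagnostics over candidate soft powers
#'
#' For each power, the adjacency, per-gene connectivity
#' `k_i = sum_{j != i} a_ij` and the scale-free topology fit — the r^2 of
#' `log10 p(k)` against `log10 k` over connectivity bins — are computed.
#' This is a diagnostic table, not an automatic selector; the default
#' pipeline power stays at 6.
#'
#' @param expr Genes x samples expression matrix (>= 10 samples advised).
#' @param candidate_powers Integer vector of powers to evaluate.
#' @param n_bins Number of connectivity bins (default 10; fits with fewer
#'   than 2 usable bins report `NA`).
#' @inheritParams adjacency_matrix
#' @return Data frame with columns `power`, `scale_free_R2`,
#'   `mean_connectivity`.
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, 12, 14, 16),
                                network_type = c("unsigned", "signed"),
                                n_bins = 10) {
  network_type <- match.arg(network_type)
  r <- suppressWarnings(stats::cor(t(expr)))
  r[is.na(r)] <- 0
  diag(r) <- 0
  base <- if (network_type == "unsigned") abs(r) else (1 + r) / 2
  out <- lapply(candidate_powers, function(beta) {
    k <- rowSums(base^beta)
    data.frame(power = beta,
               scale_free_R2 = scale_free_fit(k, n_bins),
               mean_connectivity = mean(k))
  })
  do.call(rbind, out)
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  pk <- tabulate(bin, nbins = n_bins) / length(k)
  mid <- tapply(k, bin, mean)
  use <- pk > 0 & !is.na(mid) & mid > 0
  if (sum(use) < 2) return(NA_real_)
  summary(stats::lm(log10(pk[use]) ~ log10(mid[use])))$r.squared
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j with `TOM_ii = 1`, where `k` is connectivity excluding the
#' diagonal.  The result is symmetric with entries in [0, 1]; `1 - TOM` is
#' the clustering distance used for module detection.
#'
#' @param adjacency Symmetric matrix with unit diagonal, entries in [0, 1].
#' @return The TOM matrix.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  if (!is.matrix(a) || nrow(a) != ncol(a) ||
      max(abs(a - t(a))) > 1e-10)
    stop("adjacency must be a symmetric square matrix")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  if (any(abs(diag(a) - 1) > 1e-10))
    stop("adjacency must have unit diagonal")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- (tom + t(tom)) / 2        # symmetrise away rounding noise
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

module_eigengene <- function(expr) {
  ## expr: genes x samples, one module; first PC across samples, unit norm,
  ## sign-aligned with the module's mean expression profile
  scaled <- t(scale(t(expr)))
  scaled[!is.finite(scaled)] <- 0
  sv <- svd(t(scaled), nu = 1, nv = 0)
  eg <- sv$u[, 1]
  avg <- colMeans(scaled)
  if (stats::cor(eg, avg) < 0) eg <- -eg
  stats::setNames(eg, colnames(expr))
}

#' Detect coexpression modules in one sample group
#'
#' Builds the soft-thresholded adjacency and TOM, clusters genes by
#' average-linkage on `1 - TOM`, cuts the tree statically at the
#' `tree_cut_quantile` of merge heights, discards clusters below
#' `min_module_size` to `"grey"`, and iteratively merges modules whose
#' eigengenes (first principal component of module expression, unit norm,
#' sign-aligned) correlate above `merge_eigengene_corr`.  Module labels
#' `M1, M2, ...` are assigned in decreasing size order, so the partition is
#' invariant to gene order up to identical labels.
#'
#' @param expr Genes x samples log2-normalised expression for one group.
#' @param config A [network_config()].
#' @param group Label stored in the result (e.g. `"normal"`).
#' @return An object of class `module_assignment`: list with `group`,
#'   `modules` (named character vector gene -> module label, `"grey"` for
#'   unassigned) and `eigengenes` (samples x modules matrix).
#' @export
detect_modules <- function(expr, config = network_config(), group = "all") {
  stopifnot(is.matrix(expr), inherits(config, "network_config"))
  genes <- rownames(expr)
  if (nrow(expr) < config$min_module_size) {
    warning("fewer genes than min_module_size; all genes grey")
    return(structure(list(group = group,
                          modules = stats::setNames(rep("grey", nrow(expr)),
                                                    genes),
                          eigengenes = NULL, config = config),
                     class = "module_assignment"))
  }
  adj <- adjacency_matrix(expr, config$soft_power, config$network_type)
  tom <- tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut_h <- static_cut_height(hc$height, config$tree_cut_quantile)
  cl <- stats::cutree(hc, h = cut_h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= config$min_module_size]
  labels <- stats::setNames(rep("grey", length(genes)), genes)
  ## provisional labels in decreasing size order
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  for (i in seq_along(keep))
    labels[cl == as.integer(keep[i])] <- sprintf("M%d", i)

  labels <- merge_close_modules(expr, labels, config$merge_eigengene_corr)
  eig <- eigengene_matrix(expr, labels)
  structure(list(group = group, modules = labels, eigengenes = eig,
                 config = config),
            class = "module_assignment")
}

eigengene_matrix <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(-as.vector(table(labels)[mods]), mods)]
  if (length(mods) == 0) return(NULL)
  sapply(mods, function(m)
    module_eigengene(expr[names(labels)[labels == m], , drop = FALSE]))
}

merge_close_modules <- function(expr, labels, merge_corr) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    eig <- sapply(mods, function(m)
      module_eigengene(expr[names(labels)[labels == m], , drop = FALSE]))
    cc <- stats::cor(eig)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[top[1], top[2]] <= merge_corr) break
    a <- mods[top[1]]; b <- mods[top[2]]
    labels[labels == b] <- a
  }
  ## relabel in decreasing size order for determinism
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(-as.vector(table(labels)[mods]), mods)]
  remap <- stats::setNames(sprintf("M%d", seq_along(mods)), mods)
  out <- labels
  out[labels != "grey"] <- remap[labels[labels != "grey"]]
  out
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$modules)
  cat("module_assignment (", x$group, "): ",
      sum(names(tab) != "grey"), " modules, ",
      if ("grey" %in% names(tab)) tab[["grey"]] else 0, " grey genes\n",
      sep = "")
  print(tab)
  invisible(x)
}

#' Cross-tabulate two module assignments
#'
#' Counts shared genes for every pair of modules from two group-specific
#' assignments (including grey) on the common gene universe and attaches a
#' hypergeometric upper-tail overlap p-value per pair — the benchmark for
#' how normal-group modules dissolve or persist in the cancer network.
#'
#' @param normal,cancer `module_assignment` objects with overlapping gene
#'   universes.
#' @return Data frame with columns `module_normal`, `module_cancer`,
#'   `n_shared`, `n_normal`, `n_cancer`, `universe`, `p_overlap`.
#' @export
module_overlap_table <- function(normal, cancer) {
  stopifnot(inherits(normal, "module_assignment"),
            inherits(cancer, "module_assignment"))
  common <- intersect(names(normal$modules), names(cancer$modules))
  if (length(common) == 0) stop("module assignments share no genes")
  a <- normal$modules[common]
  b <- cancer$modules[common]
  tab <- table(a, b)
  out <- expand.grid(module_normal = rownames(tab),
                     module_cancer = colnames(tab),
                     stringsAsFactors = FALSE)
  out$n_shared <- as.vector(tab)
  out$n_normal <- as.vector(table(a)[out$module_normal])
  out$n_cancer <- as.vector(table(b)[out$module_cancer])
  out$universe <- length(common)
  out$p_overlap <- mapply(hyper_upper_tail, out$n_shared, out$n_normal,
                          out$n_cancer, out$universe)
  out[order(out$module_normal, out$module_cancer), ]
}
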