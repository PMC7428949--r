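#' Fisher-z test for the difference of two correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, compared to a
#' standard normal, two-sided.  This is the between-group statistic of
#' differential gene correlation analysis.
#'
#' @param r1,r2 Pearson correlations in the two groups.
#' @param n1,n2 Group sample sizes (must exceed 3).
#' @return List with elements `z` and `p`.
#' @export
fisher_z_test <- function(r1, r2, n1, n2) {
  stopifnot(n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

cor_t_pvalue <- function(r, n) {
  ## two-sided t test of H0: rho = 0 (the within-group edge test)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Pairwise differential correlation between two groups
#'
#' For every pair of genes in `gene_subset`, computes the Pearson
#' correlation per group, its within-group two-sided t-test p-value, and
#' the Fisher-z difference statistic between groups.  Pairs involving a
#' gene that is constant in either group carry `NA` statistics.  Positive
#' `z_diff` means the correlation is stronger in the first (normal) group.
#'
#' @param expr_normal,expr_cancer Genes x samples log2-normalised
#'   expression matrices (>= 4 samples per group).
#' @param gene_subset Character vector of genes to analyse (present in both
#'   matrices).  All pairs within the subset are tested; an all-gene run
#'   warns about its quadratic cost.
#' @param adjust If `TRUE`, append BH-adjusted `p_diff_adj` (off by
#'   default).
#' @return Data frame with columns `gene_a`, `gene_b`, `r_normal`,
#'   `r_cancer`, `n_normal`, `n_cancer`, `p_normal`, `p_cancer`, `z_diff`,
#'   `p_diff` (one row per unordered pair, `gene_a < gene_b`).
#' @export
diffcorr <- function(expr_normal, expr_cancer,
                     gene_subset = rownames(expr_normal),
                     adjust = FALSE) {
  n1 <- ncol(expr_normal); n2 <- ncol(expr_cancer)
  if (n1 < 4 || n2 < 4) stop("need at least 4 samples per group")
  missing_g <- setdiff(gene_subset,
                       intersect(rownames(expr_normal),
                                 rownames(expr_cancer)))
  if (length(missing_g) > 0)
    stop("genes absent from a group: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  if (length(gene_subset) > 1000)
    warning("all-pairs differential correlation over ",
            length(gene_subset), " genes is quadratic in cost")
  e1 <- expr_normal[gene_subset, , drop = FALSE]
  e2 <- expr_cancer[gene_subset, , drop = FALSE]
  const1 <- apply(e1, 1, stats::sd) == 0
  const2 <- apply(e2, 1, stats::sd) == 0
  r1 <- suppressWarnings(stats::cor(t(e1)))
  r2 <- suppressWarnings(stats::cor(t(e2)))
  idx <- which(upper.tri(r1), arr.ind = TRUE)
  ga <- gene_subset[idx[, 1]]; gb <- gene_subset[idx[, 2]]
  ra <- r1[idx]; rb <- r2[idx]
  bad <- const1[idx[, 1]] | const1[idx[, 2]] |
    const2[idx[, 1]] | const2[idx[, 2]]
  ra[bad] <- NA; rb[bad] <- NA
  ## clamp |r| = 1 away from the atanh pole
  eps <- 1e-12
  fz <- fisher_z_test(pmin(pmax(ra, -1 + eps), 1 - eps),
                      pmin(pmax(rb, -1 + eps), 1 - eps), n1, n2)
  res <- data.frame(gene_a = pmin(ga, gb), gene_b = pmax(ga, gb),
                    r_normal = ra, r_cancer = rb,
                    n_normal = n1, n_cancer = n2,
                    p_normal = cor_t_pvalue(ra, n1),
                    p_cancer = cor_t_pvalue(rb, n2),
                    z_diff = fz$z, p_diff = fz$p,
                    stringsAsFactors = FALSE)
  if (adjust) res$p_diff_adj <- bh_adjust(res$p_diff)
  res[order(res$gene_a, res$gene_b), ]
}

#' Per-group correlation edge lists under the edge filter
#'
#' Keeps, per group, the pairs with `|r| > min_abs_r` and within-group
#' `p < max_p` (both strict), and appends each node's degree — the
#' Cytoscape-importable networks behind the module-disruption comparison.
#'
#' @param results Data frame from [diffcorr()].
#' @param min_abs_r,max_p Edge filter (defaults 0.3 and 0.05).
#' @return Named list of two data frames (`normal`, `cancer`) with columns
#'   `gene_a`, `gene_b`, `r`, `p`, `sign`, `degree_a`, `degree_b`.
#' @export
export_group_networks <- function(results, min_abs_r = 0.3, max_p = 0.05) {
  stopifnot(min_abs_r >= 0, min_abs_r < 1, max_p > 0)
  per_group <- function(r, p) {
    keep <- !is.na(r) & abs(r) > min_abs_r & p < max_p
    edges <- data.frame(gene_a = results$gene_a[keep],
                        gene_b = results$gene_b[keep],
                        r = r[keep], p = p[keep],
                        sign = ifelse(r[keep] >= 0, "positive", "negative"),
                        stringsAsFactors = FALSE)
    deg <- table(c(edges$gene_a, edges$gene_b))
    edges$degree_a <- as.integer(deg[edges$gene_a])
    edges$degree_b <- as.integer(deg[edges$gene_b])
    edges
  }
  list(normal = per_group(results$r_normal, results$p_normal),
       cancer = per_group(results$r_cancer, results$p_cancer))
}
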