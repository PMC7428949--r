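#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over genes (restricted to genes
#' with a positive across-sample geometric mean) of the ratio of the gene's
#' count in sample j to its geometric mean; the median is taken on the log
#' scale (the DESeq2 convention, which matters only when the middle ratios
#' are averaged).  Factors are not renormalised afterwards.
#'
#' @param cm A [count_matrix()].
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  log_geo <- rowMeans(log(counts))          # -Inf where any count is 0
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene has positive counts in every sample; ",
         "size factors undefined (consider a pseudo-reference fallback)")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnts)
    exp(stats::median(log(cnts) - log_geo[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor estimated; data too sparse")
  sf
}

#' Log2 normalised expression
#'
#' `log2(count / s_j + 1)` — the expression scale used by QC, network
#' construction and differential correlation.
#'
#' @param cm A [count_matrix()].
#' @param sf Optional precomputed size factors (default [size_factors()]).
#' @return Numeric matrix, genes x samples.
#' @export
normalized_log2 <- function(cm, sf = size_factors(cm)) {
  log2(sweep(cm$counts, 2, sf, `/`) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving.  `NA` p-values stay `NA` and do not count towards the
#' number of tests.
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Adjusted p-values, same order and length as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Gene-wise method-of-moments dispersion on normalised counts, shrunk
# towards a least-squares trend alpha(mu) = a0 + a1/mu fitted over
# well-estimated genes; final alpha is the midpoint of the gene-wise and
# trend values, floored at 1e-8.
estimate_dispersions <- function(counts, sf, group) {
  norm <- sweep(counts, 2, sf, `/`)
  mu_hat <- rowMeans(norm)
  xim <- mean(1 / sf)
  v <- sapply(levels(group), function(g) {
    idx <- group == g
    if (sum(idx) >= 2)
      apply(norm[, idx, drop = FALSE], 1, stats::var) * (sum(idx) - 1)
    else rep(0, nrow(norm))
  })
  df <- sum(pmax(table(group) - 1, 0))
  v_pooled <- rowSums(v) / df
  disp_mom <- pmax((v_pooled - xim * mu_hat) / mu_hat^2, 0)
  ok <- mu_hat > 1 & disp_mom > 1e-6 & disp_mom < 10
  if (sum(ok) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / mu_hat[ok]), disp_mom[ok])
    a0 <- max(fit$coefficients[1], 0)
    a1 <- max(fit$coefficients[2], 0)
  } else {
    a0 <- stats::median(disp_mom) + 1e-4; a1 <- 0
  }
  disp_trend <- a0 + a1 / mu_hat
  list(gene_wise = disp_mom, trend = disp_trend,
       trend_coef = c(a0 = a0, a1 = a1),
       final = pmax((disp_mom + disp_trend) / 2, 1e-8))
}

fit_nb_wald <- function(y, X, offset, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                    control = list(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || any(!is.finite(fit$coefficients)))
    return(c(NA_real_, NA_real_))
  ## Wald SE from the unscaled covariance of the IRLS system
  Rmat <- fit$qr$qr[seq_len(ncol(X)), , drop = FALSE]
  XtWXinv <- tryCatch(chol2inv(Rmat), error = function(e) NULL)
  if (is.null(XtWXinv)) return(c(NA_real_, NA_real_))
  c(fit$coefficients[2], sqrt(XtWXinv[2, 2]))
}

#' Negative-binomial differential expression (Wald test)
#'
#' The DESeq2-style core: median-of-ratios normalisation, gene-wise
#' method-of-moments dispersion shrunk towards a fitted 1/mu trend, an NB
#' log-link GLM per gene with design `~ group`, a Wald z test on the group
#' coefficient, and Benjamini-Hochberg adjustment over tested genes.
#' Genes with zero counts in every sample are dropped before testing.
#' Positive log2 fold-changes mean higher expression in the contrast
#' (cancer) group.
#'
#' @param cm A [count_matrix()] with at least 2 samples in each group.
#' @return A data frame with one row per tested gene and columns `gene_id`,
#'   `baseMean` (mean of normalised counts over all samples),
#'   `log2FoldChange`, `lfcSE`, `pvalue`, `padj`.  Non-convergent genes
#'   carry `NA` statistics and are excluded from the BH test count.
#' @export
de_test <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- table(cm$groups)
  if (any(tab < 2))
    stop("each group needs at least 2 samples; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  keep <- rowSums(cm$counts) > 0
  counts <- cm$counts[keep, , drop = FALSE]
  sf <- size_factors(cm)
  group <- cm$groups
  disp <- estimate_dispersions(counts, sf, group)
  X <- stats::model.matrix(~ group)
  offset <- log(sf)
  ln2 <- log(2)
  est <- t(vapply(seq_len(nrow(counts)), function(i)
    fit_nb_wald(counts[i, ], X, offset, disp$final[i]),
    numeric(2)))
  lfc <- est[, 1] / ln2
  se <- est[, 2] / ln2
  z <- est[, 1] / est[, 2]
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(gene_id = rownames(counts),
                    baseMean = rowMeans(sweep(counts, 2, sf, `/`)),
                    log2FoldChange = lfc,
                    lfcSE = se,
                    pvalue = p,
                    padj = bh_adjust(p),
                    row.names = NULL)
  attr(res, "size_factors") <- sf
  attr(res, "dispersion_trend") <- disp$trend_coef
  res
}

#' Threshold tiers for DE gene selection
#'
#' @param padj_max Loose-tier adjusted-p cutoff (strict `<`).
#' @param strict_padj_max,strict_basemean_min,strict_lfc_min Strict-tier
#'   cutoffs (`padj <= strict_padj_max`, `baseMean >= strict_basemean_min`,
#'   `|log2FoldChange| >= strict_lfc_min`).
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(padj_max = 0.05, strict_padj_max = 0.001,
                          strict_basemean_min = 100, strict_lfc_min = 1) {
  stopifnot(padj_max > 0, strict_padj_max > 0, strict_basemean_min > 0,
            strict_lfc_min > 0, strict_padj_max <= padj_max)
  structure(list(padj_max = padj_max, strict_padj_max = strict_padj_max,
                 strict_basemean_min = strict_basemean_min,
                 strict_lfc_min = strict_lfc_min),
            class = "de_thresholds")
}

#' Select up/down DE gene sets at a threshold tier
#'
#' The loose tier keeps genes with `padj < padj_max`, split by fold-change
#' sign; the strict tier additionally requires
#' `padj <= strict_padj_max`, `baseMean >= strict_basemean_min` and
#' `|log2FoldChange| >= strict_lfc_min`.  The strict sets are always
#' subsets of the loose ones.
#'
#' @param results Data frame from [de_test()].
#' @param thresholds A [de_thresholds()].
#' @param tier `"loose"` or `"strict"`.
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
apply_thresholds <- function(results, thresholds = de_thresholds(),
                             tier = c("loose", "strict")) {
  tier <- match.arg(tier)
  stopifnot(inherits(thresholds, "de_thresholds"))
  ok <- !is.na(results$padj) & !is.na(results$log2FoldChange)
  sel <- ok & results$padj < thresholds$padj_max
  if (tier == "strict")
    sel <- sel & results$padj <= thresholds$strict_padj_max &
      results$baseMean >= thresholds$strict_basemean_min &
      abs(results$log2FoldChange) >= thresholds$strict_lfc_min
  list(up = results$gene_id[sel & results$log2FoldChange > 0],
       down = results$gene_id[sel & results$log2FoldChange < 0])
}
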