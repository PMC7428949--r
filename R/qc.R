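qc_report <- function(method, kept, removed, scores, parameters) {
  structure(list(method = method, kept_sample_ids = kept,
                 removed_sample_ids = removed, scores = scores,
                 parameters = parameters),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report (", x$method, "): kept ", length(x$kept_sample_ids),
      ", removed ", length(x$removed_sample_ids), sep = "")
  if (length(x$removed_sample_ids) > 0)
    cat(" [", paste(x$removed_sample_ids, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' PCA outlier screen
#'
#' Samples are projected onto the first `n_pcs` principal components of
#' their log2-normalised profiles; each component is centred at its median
#' and scaled by its MAD, so a sample's robust distance accumulates how
#' aberrant it is on every leading axis of variation regardless of that
#' axis's magnitude (an outlier typically owns a minor component, which
#' plain Euclidean distance on the top components would overlook in the
#' presence of strong group or module structure).  A sample is removed iff
#' its distance exceeds `median(d) + mad_k * MAD(d)`.  The rule is
#' scale-free and deterministic; `mad_k = Inf` disables removal.
#'
#' @param cm A [count_matrix()] with at least 4 samples.
#' @param n_pcs Number of leading principal components; the default `NULL`
#'   uses `min(10, n_samples - 1)`.  Requesting `n_pcs >= n_samples` is an
#'   error.
#' @param mad_k Robust cutoff multiplier (default 8; on the standardised
#'   distance scale this sits far outside the null spread while remaining
#'   well below a genuinely aberrant profile's distance).
#' @return A `qc_report` with per-sample PC coordinates, distances and the
#'   cutoff used.
#' @export
pca_outliers <- function(cm, n_pcs = NULL, mad_k = 8) {
  stopifnot(inherits(cm, "count_matrix"))
  n <- ncol(cm$counts)
  if (n < 4) stop("PCA QC needs at least 4 samples")
  if (is.null(n_pcs)) n_pcs <- min(10L, n - 1L)
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of samples")
  if (mad_k <= 0) stop("mad_k must be positive")
  expr <- normalized_log2(cm)
  pca <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(min(n_pcs, ncol(pca$x))), drop = FALSE]
  centred <- sweep(scores, 2, apply(scores, 2, stats::median))
  scale_ <- apply(scores, 2, stats::mad)
  use <- scale_ > 0
  d <- if (any(use))
    sqrt(rowSums(sweep(centred[, use, drop = FALSE], 2,
                       scale_[use], `/`)^2))
  else stats::setNames(rep(0, n), rownames(scores))
  cutoff <- if (is.infinite(mad_k)) Inf else
    stats::median(d) + mad_k * stats::mad(d)
  removed <- names(d)[d > cutoff]
  kept <- setdiff(colnames(cm$counts), removed)
  qc_report("pca", kept, removed,
            data.frame(sample_id = rownames(scores), scores,
                       distance = unname(d), row.names = NULL),
            list(n_pcs = n_pcs, mad_k = mad_k, cutoff = cutoff))
}

#' Dendrogram outlier screen
#'
#' Average-linkage hierarchical clustering of samples on Euclidean
#' distances of log2-normalised profiles; the tree is cut at `cut_height`
#' and every sample outside the largest resulting cluster is removed (the
#' standard WGCNA outlier-removal recipe).  The default cut height is the
#' 99th percentile of the tree's merge heights, since absolute heights do
#' not transfer across datasets.
#'
#' @param cm A [count_matrix()] with at least 3 samples.
#' @param cut_height Positive height at which to cut the tree, or `NULL`
#'   for the automatic default.
#' @return A `qc_report`; `scores` holds each sample's merge height into
#'   the tree.
#' @export
dendrogram_outliers <- function(cm, cut_height = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 3) stop("dendrogram QC needs at least 3 samples")
  expr <- normalized_log2(cm)
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  if (is.null(cut_height))
    cut_height <- stats::quantile(hc$height, 0.99, names = FALSE)
  if (cut_height <= 0) stop("cut_height must be positive")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  main <- as.integer(names(sizes)[which.max(sizes)])
  removed <- names(cl)[cl != main]
  kept <- setdiff(colnames(cm$counts), removed)
  ## height at which each sample is first merged into the tree
  merge_h <- stats::setNames(rep(NA_real_, ncol(cm$counts)),
                             colnames(cm$counts))
  for (i in seq_len(nrow(hc$merge))) {
    leaves <- -hc$merge[i, ][hc$merge[i, ] < 0]
    merge_h[hc$labels[leaves]] <- hc$height[i]
  }
  qc_report("dendrogram", kept, removed,
            data.frame(sample_id = names(merge_h),
                       merge_height = unname(merge_h), row.names = NULL),
            list(cut_height = cut_height))
}

#' Apply a QC report to a count matrix
#'
#' @param cm A [count_matrix()].
#' @param report A `qc_report` from [pca_outliers()] or
#'   [dendrogram_outliers()].
#' @return The `count_matrix` restricted to kept samples.
#' @export
apply_qc <- function(cm, report) {
  stopifnot(inherits(report, "qc_report"))
  subset_counts(cm, samples = report$kept_sample_ids)
}
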