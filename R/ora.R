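#' Hypergeometric upper-tail probability of an overlap
#'
#' `P(X >= overlap)` where `X` is the overlap of a random list of
#' `list_size` genes with a fixed set of `set_size` genes drawn from a
#' universe of `universe_size`.  Identical to a one-sided (enrichment)
#' Fisher exact test on the 2x2 overlap table.
#'
#' @param overlap,list_size,set_size,universe_size Non-negative integer
#'   table margins; `overlap` may not exceed either margin and the implied
#'   2x2 cells must be non-negative.
#' @return The upper-tail p-value.
#' @export
hyper_upper_tail <- function(overlap, list_size, set_size, universe_size) {
  if (overlap < 0 || list_size < 0 || set_size < 0 || universe_size < 0)
    stop("counts must be non-negative")
  if (overlap > min(list_size, set_size))
    stop("overlap exceeds a margin")
  if (universe_size - list_size - set_size + overlap < 0)
    stop("inconsistent margins: negative 2x2 cell")
  stats::phyper(overlap - 1, set_size, universe_size - set_size, list_size,
                lower.tail = FALSE)
}

#' Over-representation analysis of a gene list against a GMT collection
#'
#' One-sided hypergeometric test per gene set: is the overlap between the
#' query list and the set larger than expected for a random list of the
#' same size drawn from the universe?  Collection sets are intersected
#' with the universe first; BH adjustment is computed across all tested
#' sets, and results are sorted by p.
#'
#' @param gene_list Character vector of query genes (must lie within
#'   `universe`).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector: the tested background, typically all
#'   genes surviving the all-zero filter.
#' @param p_max Raw-p significance flag threshold (default 0.001).
#' @return Data frame with columns `gene_set_id`, `overlap_count`,
#'   `list_size`, `set_size`, `universe_size`, `p`, `padj`, `significant`,
#'   `overlapping_genes` (comma-separated), sorted by `p`.
#' @export
ora <- function(gene_list, collection, universe, p_max = 0.001) {
  if (length(universe) == 0) stop("empty universe")
  if (length(gene_list) == 0) stop("empty gene list")
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  stray <- setdiff(gene_list, universe)
  if (length(stray) > 0)
    stop("gene list members outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  rows <- lapply(names(collection), function(id) {
    set <- intersect(collection[[id]], universe)
    ov <- intersect(gene_list, set)
    p <- if (length(set) == 0) 1 else
      hyper_upper_tail(length(ov), length(gene_list), length(set),
                       length(universe))
    data.frame(gene_set_id = id, overlap_count = length(ov),
               list_size = length(gene_list), set_size = length(set),
               universe_size = length(universe), p = p,
               overlapping_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$p)
  res$significant <- res$p < p_max
  res <- res[order(res$p, res$gene_set_id),
             c("gene_set_id", "overlap_count", "list_size", "set_size",
               "universe_size", "p", "padj", "significant",
               "overlapping_genes")]
  rownames(res) <- NULL
  res
}

#' Batch ORA over every module of a module assignment
#'
#' @param assignment A `module_assignment` from [detect_modules()].
#' @param collection,universe,p_max As in [ora()].
#' @return Data frame: [ora()] output with a leading `module` column,
#'   stacked over all non-grey modules.
#' @export
ora_modules <- function(assignment, collection, universe, p_max = 0.001) {
  stopifnot(inherits(assignment, "module_assignment"))
  mods <- setdiff(unique(assignment$modules), "grey")
  out <- lapply(sort(mods), function(m) {
    genes <- intersect(names(assignment$modules)[assignment$modules == m],
                       universe)
    if (length(genes) == 0) return(NULL)
    cbind(module = m, ora(genes, collection, universe, p_max))
  })
  do.call(rbind, out)
}
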