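#' Construct a validated count matrix
#'
#' The root input of the pipeline: an integer gene-by-sample read-count
#' matrix plus a group label (e.g. `"normal"` / `"cancer"`) per sample.
#'
#' @param counts Numeric matrix of non-negative integers, genes in rows and
#'   samples in columns, with unique row and column names.
#' @param groups Character or factor vector of group labels, one per sample.
#'   May be named by sample id; otherwise taken in column order.
#' @param group_levels Length-2 character vector giving the reference
#'   (baseline) and contrast group labels, in that order.  Fold changes are
#'   reported as contrast versus reference.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `groups` (factor named by sample id,
#'   levels `group_levels`).
#' @export
count_matrix <- function(counts, groups,
                         group_levels = c("normal", "cancer")) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("counts must be non-negative integers; first offender: gene '",
         rownames(counts)[bad[1, 1]], "', sample '",
         colnames(counts)[bad[1, 2]], "' (value ",
         counts[bad[1, 1], bad[1, 2]], ")")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(names(groups))) {
    missing_g <- setdiff(colnames(counts), names(groups))
    if (length(missing_g) > 0)
      stop("samples without a group label: ",
           paste(missing_g, collapse = ", "))
    groups <- groups[colnames(counts)]
  } else if (length(groups) != ncol(counts)) {
    stop("groups must have one label per sample")
  }
  groups <- as.character(groups)
  outside <- setdiff(unique(groups), group_levels)
  if (length(outside) > 0)
    stop("group labels outside {", paste(group_levels, collapse = ", "),
         "}: ", paste(outside, collapse = ", "))
  groups <- factor(groups, levels = group_levels)
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  print(table(x$groups))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or samples
#'
#' @param cm A [count_matrix()].
#' @param genes,samples Character vectors of ids to keep (default: all).
#' @return A `count_matrix` restricted to the requested ids.
#' @export
subset_counts <- function(cm, genes = rownames(cm$counts),
                          samples = colnames(cm$counts)) {
  stopifnot(inherits(cm, "count_matrix"))
  missing_g <- setdiff(genes, rownames(cm$counts))
  if (length(missing_g) > 0)
    stop("unknown gene ids: ", paste(utils::head(missing_g, 5), collapse = ", "))
  missing_s <- setdiff(samples, colnames(cm$counts))
  if (length(missing_s) > 0)
    stop("unknown sample ids: ", paste(utils::head(missing_s, 5), collapse = ", "))
  count_matrix(cm$counts[genes, samples, drop = FALSE],
               stats::setNames(as.character(cm$groups[samples]), samples),
               group_levels = levels(cm$groups))
}

#' Read a count matrix and sample metadata from TSV files
#'
#' The counts file has a header row of sample ids and gene ids in the first
#' column; the metadata file has columns `sample_id` and `group`.  Samples
#' present in the counts but absent from the metadata are an error, never a
#' silent drop; extra metadata rows are ignored.
#'
#' @param counts_path,metadata_path Paths to the TSV files.
#' @inheritParams count_matrix
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, metadata_path,
                        group_levels = c("normal", "cancer")) {
  for (p in c(counts_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  gene_ids <- tab[[1]]
  mat <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(gene_ids, colnames(mat))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric count for gene '", gene_ids[bad[1]], "', sample '",
         colnames(num)[bad[2]], "'")
  }
  meta <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            comment.char = "")
  if (!all(c("sample_id", "group") %in% colnames(meta)))
    stop("metadata must have columns sample_id and group")
  missing_s <- setdiff(colnames(num), meta$sample_id)
  if (length(missing_s) > 0)
    stop("samples in counts missing from metadata: ",
         paste(missing_s, collapse = ", "))
  groups <- stats::setNames(meta$group, meta$sample_id)
  count_matrix(num, groups[colnames(num)], group_levels = group_levels)
}

#' Write a count matrix (and its metadata) to TSV
#'
#' @param cm A [count_matrix()].
#' @param counts_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(cm, counts_path, metadata_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = names(cm$groups),
                     group = as.character(cm$groups))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated, with the set id in
#' column 1, a free-text description in column 2 and member genes after.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene ids, with a
#'   `description` attribute on each element.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(utils::head(which(short), 5), collapse = ", "))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("empty gene set for id '", f[[1]], "'")
    if (anyDuplicated(genes))
      stop("duplicate genes within set '", f[[1]], "'")
    attr(genes, "description") <- f[[2]]
    genes
  })
  stats::setNames(sets, ids)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (optionally carrying a
#'   `description` attribute).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(id) {
    genes <- sets[[id]]
    desc <- attr(genes, "description")
    if (is.null(desc)) desc <- id
    paste(c(id, desc, as.character(genes)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a paired up/down signature library
#'
#' A signature library maps each perturbagen (drug, or the disease itself)
#' to a pair of disjoint gene sets: genes up-regulated and genes
#' down-regulated by the perturbation.
#'
#' @param entries Named list; each element a list with character-vector
#'   elements `up` and `down` (optionally `description`).
#' @param universe Optional explicit gene universe (character vector).
#' @return An object of class `signature_library`.
#' @export
signature_library <- function(entries, universe = NULL) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  for (id in names(entries)) {
    e <- entries[[id]]
    if (length(e$up) == 0 || length(e$down) == 0)
      stop("empty up or down set for '", id, "'")
    both <- intersect(e$up, e$down)
    if (length(both) > 0)
      stop("gene(s) in both directions for '", id, "': ",
           paste(utils::head(both, 5), collapse = ", "))
  }
  structure(list(entries = entries, universe = universe),
            class = "signature_library")
}

#' @export
print.signature_library <- function(x, ...) {
  sz <- vapply(x$entries, function(e) length(e$up) + length(e$down), 1L)
  cat("signature_library: ", length(x$entries), " perturbagens, ",
      "median signature size ", stats::median(sz), "\n", sep = "")
  invisible(x)
}

#' Read a paired up/down signature library from two GMT files
#'
#' @param path_up,path_down Parallel GMT files holding, per perturbagen id,
#'   the up- and down-regulated gene sets.  The same ids must appear in
#'   both files.
#' @return A [signature_library()].
#' @export
read_signatures_gmt <- function(path_up, path_down) {
  up <- read_gmt(path_up)
  down <- read_gmt(path_down)
  only_up <- setdiff(names(up), names(down))
  only_down <- setdiff(names(down), names(up))
  if (length(only_up) > 0 || length(only_down) > 0)
    stop("perturbagen ids present in only one direction file: ",
         paste(utils::head(c(only_up, only_down), 5), collapse = ", "))
  entries <- lapply(names(up), function(id) {
    list(up = as.character(up[[id]]), down = as.character(down[[id]]),
         description = attr(up[[id]], "description"))
  })
  signature_library(stats::setNames(entries, names(up)))
}

#' Write a signature library as two parallel GMT files
#'
#' @param lib A [signature_library()].
#' @param path_up,path_down Output GMT paths for the up and down sets.
#' @return Invisibly, the two paths.
#' @export
write_signatures_gmt <- function(lib, path_up, path_down) {
  stopifnot(inherits(lib, "signature_library"))
  mk <- function(dir) {
    lapply(lib$entries, function(e) {
      g <- e[[dir]]
      attr(g, "description") <- if (is.null(e$description)) "" else e$description
      g
    })
  }
  write_gmt(mk("up"), path_up)
  write_gmt(mk("down"), path_down)
  invisible(c(path_up, path_down))
}

#' Write a result table as TSV
#'
#' Fixed column order, no quoting, no row names — the on-disk contract for
#' every stage output.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
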