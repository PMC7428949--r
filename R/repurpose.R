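#' Construct a disease signature
#'
#' The disease's up/down DE gene sets plus the analysis universe, usually
#' produced from [de_test()] output via [apply_thresholds()].
#'
#' @param up,down Disjoint character vectors of up- and down-regulated
#'   genes.
#' @param universe Character vector containing both sets: the measurable
#'   gene background.
#' @param tier Which threshold tier produced the sets (metadata).
#' @return A list of class `disease_signature`.
#' @export
disease_signature <- function(up, down, universe,
                              tier = c("loose", "strict")) {
  tier <- match.arg(tier)
  up <- unique(up); down <- unique(down); universe <- unique(universe)
  if (length(intersect(up, down)) > 0)
    stop("up and down sets overlap")
  stray <- setdiff(c(up, down), universe)
  if (length(stray) > 0)
    stop("signature genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  structure(list(up = up, down = down, universe = universe, tier = tier),
            class = "disease_signature")
}

#' Direction-reversed overlap counts
#'
#' Counts only the reversed pairings — disease-up genes in the drug's down
#' set and disease-down genes in the drug's up set — after restricting the
#' drug sets to the disease universe.  Concordant overlaps are not counted:
#' a repurposing candidate must push the disease signature back, not
#' further.
#'
#' @param disease A [disease_signature()].
#' @param drug_up,drug_down The drug's up/down gene sets.
#' @return Named integer vector `c(o_rev_updown, o_rev_downup)`: disease-up
#'   vs drug-down, and disease-down vs drug-up.
#' @export
reversal_overlap <- function(disease, drug_up, drug_down) {
  stopifnot(inherits(disease, "disease_signature"))
  drug_up <- intersect(drug_up, disease$universe)
  drug_down <- intersect(drug_down, disease$universe)
  c(o_rev_updown = length(intersect(disease$up, drug_down)),
    o_rev_downup = length(intersect(disease$down, drug_up)))
}

#' One-sided Fisher exact p for a reversal overlap
#'
#' The pooled test: total reversed overlap `o_total` against the combined
#' disease signature size and combined drug signature size, on the 2x2
#' table `[[o, drug - o], [disease - o, U - drug - disease + o]]` —
#' equivalent to the hypergeometric upper tail `P(X >= o_total)`.
#'
#' @param o_total Total reversed overlap.
#' @param disease_size `|up| + |down|` of the disease signature.
#' @param drug_sig_size Drug signature size after universe restriction.
#' @param universe_size Size of the analysis universe.
#' @return The one-sided p-value.
#' @export
fisher_reversal_p <- function(o_total, disease_size, drug_sig_size,
                              universe_size) {
  hyper_upper_tail(o_total, drug_sig_size, disease_size, universe_size)
}

#' Rank a drug library by signature reversal
#'
#' Scores every drug: reversed-overlap counts, pooled one-sided Fisher
#' exact p, and coverage (the fraction of the drug's own signature that
#' overlaps the disease signature in the reversed direction).  Passing
#' drugs satisfy `fisher_p < p_max` and `coverage > cov_min` (both strict)
#' and are ranked by coverage descending, ties broken by ascending
#' `fisher_p`, then drug id.
#'
#' @param disease A [disease_signature()].
#' @param library A [signature_library()].
#' @param p_max Fisher-p filter (default 1e-5).
#' @param cov_min Coverage filter (default 0.95).
#' @param restrict_coverage If `TRUE` (default), the coverage denominator
#'   is the drug signature restricted to the analysis universe; `FALSE`
#'   uses the unrestricted signature size.
#' @return Data frame with one row per drug and columns `drug_id`,
#'   `o_rev_updown`, `o_rev_downup`, `o_total`, `drug_sig_size`,
#'   `fisher_p`, `coverage`, `passes_p`, `passes_coverage`, `rank` (1..k
#'   over passing drugs, `NA` otherwise), sorted passing-first.
#' @export
rank_drugs <- function(disease, library, p_max = 1e-5, cov_min = 0.95,
                       restrict_coverage = TRUE) {
  stopifnot(inherits(disease, "disease_signature"),
            inherits(library, "signature_library"))
  if (length(library$entries) == 0) stop("empty drug library")
  U <- length(disease$universe)
  dsize <- length(disease$up) + length(disease$down)
  rows <- lapply(names(library$entries), function(id) {
    e <- library$entries[[id]]
    up <- intersect(e$up, disease$universe)
    down <- intersect(e$down, disease$universe)
    sig_size <- length(up) + length(down)
    ov <- reversal_overlap(disease, e$up, e$down)
    o <- sum(ov)
    if (sig_size == 0) {
      warning("drug '", id, "' has an empty signature after universe ",
              "restriction; excluded from the passing set")
      return(data.frame(drug_id = id, o_rev_updown = ov[[1]],
                        o_rev_downup = ov[[2]], o_total = o,
                        drug_sig_size = 0L, fisher_p = NA_real_,
                        coverage = NA_real_, stringsAsFactors = FALSE))
    }
    denom <- if (restrict_coverage) sig_size else
      length(e$up) + length(e$down)
    data.frame(drug_id = id, o_rev_updown = ov[[1]], o_rev_downup = ov[[2]],
               o_total = o, drug_sig_size = sig_size,
               fisher_p = fisher_reversal_p(o, dsize, sig_size, U),
               coverage = o / denom, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$passes_p <- !is.na(res$fisher_p) & res$fisher_p < p_max
  res$passes_coverage <- !is.na(res$coverage) & res$coverage > cov_min
  pass <- res$passes_p & res$passes_coverage
  ord <- order(-pass, -res$coverage, res$fisher_p, res$drug_id,
               na.last = TRUE)
  res <- res[ord, ]
  res$rank <- NA_integer_
  res$rank[res$passes_p & res$passes_coverage] <- seq_len(sum(pass))
  rownames(res) <- NULL
  res
}
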