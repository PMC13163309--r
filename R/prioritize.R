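#' Composite gene prioritization score
#'
#' The analytical core of the pipeline: each candidate gene is scored by
#'
#' `Score = w_p * (-log10(p.adjust)) + w_e * log2(FPKM + 1) + w_r * relevance`
#'
#' with default weights (0.5, 0.3, 0.2), combining pathway-enrichment
#' significance, expression abundance and pathway-relevance weighting. The
#' formula is evaluated exactly, with no clipping; scores are kept at full
#' precision and only rounded for display.
#'
#' @param p_adjust Adjusted enrichment p-value(s), in (0, 1].
#' @param fpkm Expression abundance (FPKM), >= 0.
#' @param relevance Pathway-relevance weight, 1.0 for top-five-pathway
#'   members, 0.5 for members of other significant pathways (0 allowed only
#'   as a degenerate input).
#' @param weights Numeric length-3 vector (w_p, w_e, w_r) summing to 1.
#' @return Numeric score(s).
#' @examples
#' composite_score(1.20e-8, 50.00, 1.0)  # 5.862 at 3 dp
#' @export
composite_score <- function(p_adjust, fpkm, relevance,
                            weights = c(0.5, 0.3, 0.2)) {
  if (any(p_adjust <= 0 | p_adjust > 1))
    stop("composite_score: p_adjust must lie in (0, 1]")
  if (any(fpkm < 0)) stop("composite_score: fpkm must be non-negative")
  if (any(relevance < 0 | relevance > 1))
    stop("composite_score: relevance must lie in [0, 1]")
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-12)
    stop("composite_score: weights must be three values summing to 1")
  weights[1] * (-log10(p_adjust)) + weights[2] * log2(fpkm + 1) +
    weights[3] * relevance
}

#' Rank genes by composite score
#'
#' Scores every record with [composite_score()] and returns the top `k` in
#' descending score order. Ties are broken by `|log2fc|` descending, then
#' `gene_id` ascending, applied as a stable sort; this is a package
#' convention, since published equal-score orderings do not disclose a
#' consistent tie rule.
#'
#' @param records data.frame with columns `gene_id`, `p_adjust`, `fpkm`,
#'   `relevance`, and `log2fc` (used for tie-breaks); any further columns
#'   (e.g. `fdr`) are carried through.
#' @param k Number of top genes to keep, default 20. If `k` exceeds the
#'   number of records, all are returned with a warning.
#' @param weights Passed to [composite_score()].
#' @return data.frame of the top `k` records with `score` and `rank` columns.
#' @export
rank_genes <- function(records, k = 20L, weights = c(0.5, 0.3, 0.2)) {
  need <- c("gene_id", "p_adjust", "fpkm", "relevance", "log2fc")
  if (!all(need %in% names(records)))
    stop("rank_genes: records must have columns ",
         paste(need, collapse = ", "))
  if (nrow(records) < 1L) stop("rank_genes: at least one record required")
  records$score <- composite_score(records$p_adjust, records$fpkm,
                                   records$relevance, weights)
  ord <- order(-records$score, -abs(records$log2fc), records$gene_id)
  out <- records[ord, , drop = FALSE]
  if (k > nrow(out)) {
    warning("rank_genes: k exceeds the number of records; returning all")
    k <- nrow(out)
  }
  out <- out[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Multi-criteria target gate
#'
#' From the ranked top-k genes, keeps those that simultaneously satisfy
#' `fdr < fdr_max`, `|log2fc| >= abs_lfc_min`, rank within `top_k`, and an
#' externally supplied functional-annotation flag (documented involvement in
#' the pathways under study; never inferred by the package). Genes with no
#' flag entry are treated as unannotated (FALSE) with a warning.
#'
#' @param ranked data.frame from [rank_genes()], carrying `fdr` and `log2fc`.
#' @param annotation_flags Named logical vector keyed by gene id.
#' @param fdr_max,abs_lfc_min,top_k Gate thresholds (defaults 0.05, 0.5, 20).
#' @return Character vector of selected target gene ids, in rank order.
#' @export
select_targets <- function(ranked, annotation_flags,
                           fdr_max = 0.05, abs_lfc_min = 0.5, top_k = 20L) {
  need <- c("gene_id", "fdr", "log2fc", "rank")
  if (!all(need %in% names(ranked)))
    stop("select_targets: ranked records must have columns ",
         paste(need, collapse = ", "))
  missing_flag <- setdiff(ranked$gene_id, names(annotation_flags))
  if (length(missing_flag) > 0)
    warning("select_targets: no annotation flag for ",
            paste(utils::head(missing_flag, 5), collapse = ", "),
            "; treated as FALSE")
  flags <- stats::setNames(rep(FALSE, nrow(ranked)), ranked$gene_id)
  known <- intersect(names(annotation_flags), names(flags))
  flags[known] <- annotation_flags[known]
  keep <- ranked$fdr < fdr_max &
    abs(ranked$log2fc) >= abs_lfc_min &
    ranked$rank <= top_k &
    flags[ranked$gene_id]
  ranked$gene_id[keep]
}

#' Recompute the packaged gene-prioritization table
#'
#' Re-evaluates the composite score from the fixture's printed inputs
#' (adjusted p, FPKM, relevance) and compares against the printed score
#' column, row by row.
#'
#' @param fixture The table loaded by `load_fixture("table1")`; loaded
#'   automatically when omitted.
#' @param tol Per-row absolute tolerance used for the `matched` flag,
#'   default 5e-4 (half a unit of the 3-decimal printing).
#' @return data.frame with `gene`, `computed`, `printed`, `abs_diff`,
#'   `matched`; the maximum absolute difference is attached as attribute
#'   `max_abs_diff`.
#' @export
reproduce_table1 <- function(fixture = load_fixture("table1"), tol = 5e-4) {
  computed <- composite_score(fixture$p_adjust, fixture$fpkm,
                              fixture$relevance)
  out <- data.frame(
    gene = fixture$gene,
    computed = computed,
    printed = fixture$score,
    abs_diff = abs(computed - fixture$score),
    stringsAsFactors = FALSE
  )
  out$matched <- out$abs_diff <= tol
  attr(out, "max_abs_diff") <- max(out$abs_diff)
  out
}
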