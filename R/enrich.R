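#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set id, description,
#'   then member genes).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path)
  fgsea::gmtPathways(path)
}

#' One-sided hypergeometric over-representation test
#'
#' Tests whether a gene set is over-represented in a differentially
#' expressed gene list drawn from a finite universe. With `N` universe
#' genes, `K` set members in the universe, and `n` DEGs of which `k` fall
#' in the set, the p-value is the upper tail `P(X >= k)` of
#' Hypergeometric(N, K, n).
#'
#' @param deg_set Character vector of DEG ids; must be a subset of `universe`.
#' @param members Character vector of pathway member gene ids; only members
#'   present in the universe count toward `K`.
#' @param universe Character vector of all tested gene ids.
#' @return A list with `k`, `K`, `n`, `N` and `p_value`.
#' @examples
#' # N = 10, K = 2, n = 2, k = 2: p = 1/45
#' ora_test(c("g1", "g2"), c("g1", "g2"), paste0("g", 1:10))$p_value
#' @export
ora_test <- function(deg_set, members, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("ora_test: universe is empty")
  deg_set <- unique(deg_set)
  if (!all(deg_set %in% universe))
    stop("ora_test: deg_set must be a subset of the universe")
  K_members <- intersect(unique(members), universe)
  N <- length(universe)
  K <- length(K_members)
  n <- length(deg_set)
  k <- length(intersect(deg_set, K_members))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p_value = p)
}

#' Over-representation analysis across a pathway collection
#'
#' Applies [ora_test()] to every pathway, adjusts p-values with
#' [bh_adjust()], and assigns deterministic ranks by ascending
#' (`p_adjust`, `p_value`, `pathway_id`). A pathway is significant when
#' `p_adjust < alpha`.
#'
#' @param deg_set Character vector of DEG ids (subset of `universe`).
#' @param pathways Named list of member-gene character vectors.
#' @param universe Character vector of all tested gene ids.
#' @param alpha Significance level on the adjusted p-value, default 0.05.
#' @return data.frame ordered by rank: `pathway_id`, `k`, `K`, `n`, `N`,
#'   `p_value`, `p_adjust`, `rank`, `significant`.
#' @export
enrich_all <- function(deg_set, pathways, universe, alpha = 0.05) {
  if (length(pathways) == 0L) stop("enrich_all: at least one pathway required")
  if (is.null(names(pathways)) || any(!nzchar(names(pathways))))
    stop("enrich_all: pathways must be a named list")
  res <- lapply(names(pathways), function(id) {
    o <- ora_test(deg_set, pathways[[id]], universe)
    data.frame(pathway_id = id, k = o$k, K = o$K, n = o$n, N = o$N,
               p_value = o$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjust <- bh_adjust(res$p_value)
  ord <- order(res$p_adjust, res$p_value, res$pathway_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$significant <- res$p_adjust < alpha
  rownames(res) <- NULL
  res
}

#' Pathway-relevance weight for the composite score
#'
#' A gene receives weight 1.0 when it belongs to any of the top five
#' significant pathways (by enrichment rank), 0.5 when it belongs to any
#' other significant pathway, and 0.0 otherwise (such genes are excluded
#' from composite scoring). When fewer than five pathways are significant,
#' all significant pathways carry weight 1.0.
#'
#' @param gene_ids Character vector of genes to weight.
#' @param enrichment Ranked data.frame from [enrich_all()].
#' @param pathways The same named list of member genes used for enrichment.
#' @param top_n Number of top pathways carrying full weight, default 5.
#' @return Named numeric vector of weights in \{1.0, 0.5, 0.0\}. Genes absent
#'   from every pathway trigger a warning and get 0.0.
#' @export
assign_relevance <- function(gene_ids, enrichment, pathways, top_n = 5L) {
  sig <- enrichment$pathway_id[enrichment$significant]
  top <- utils::head(sig, top_n)
  other <- setdiff(sig, top)
  top_genes <- unique(unlist(pathways[top], use.names = FALSE))
  other_genes <- unique(unlist(pathways[other], use.names = FALSE))
  all_genes <- unique(unlist(pathways, use.names = FALSE))
  unknown <- setdiff(gene_ids, all_genes)
  if (length(unknown) > 0)
    warning("assign_relevance: gene(s) not found in any pathway: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  w <- ifelse(gene_ids %in% top_genes, 1.0,
              ifelse(gene_ids %in% other_genes, 0.5, 0.0))
  stats::setNames(w, gene_ids)
}
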