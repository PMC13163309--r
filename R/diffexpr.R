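#' RNA quality-control gate
#'
#' Accepts a sample for library preparation only if RINe >= 7 (inclusive),
#' the 28S/18S ribosomal ratio exceeds 2.0 (strict) and DV200 exceeds 70%
#' (strict). Failed criteria are enumerated by name.
#'
#' @param rine RNA integrity number equivalent.
#' @param ratio_28s_18s 28S/18S ribosomal RNA ratio.
#' @param dv200 Percentage of RNA fragments longer than 200 nt, in \[0, 100\].
#' @return A list with `pass` (logical) and `failed` (character vector of
#'   criterion names, empty when passing).
#' @examples
#' qc_gate(9.3, 2.4, 85)$pass
#' qc_gate(6.9, 2.5, 90)$failed
#' @export
qc_gate <- function(rine, ratio_28s_18s, dv200) {
  vals <- list(rine = rine, ratio_28s_18s = ratio_28s_18s, dv200 = dv200)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("qc_gate: field '%s' must be a single non-missing number", nm))
  }
  if (dv200 < 0 || dv200 > 100) stop("qc_gate: dv200 must lie in [0, 100]")
  failed <- character(0)
  if (!(rine >= 7)) failed <- c(failed, "rine")
  if (!(ratio_28s_18s > 2.0)) failed <- c(failed, "ratio_28s_18s")
  if (!(dv200 > 70)) failed <- c(failed, "dv200")
  list(pass = length(failed) == 0L, failed = failed)
}

#' Fragments per kilobase per million mapped reads
#'
#' `fpkm = count * 1e9 / (library_size * length_bp)`. Library sizes default
#' to per-sample total counts when a matrix is supplied.
#'
#' @param counts Non-negative count matrix (genes x samples) or vector.
#' @param lengths_bp Positive gene lengths in base pairs.
#' @param library_sizes Positive per-sample library sizes; defaults to
#'   `colSums(counts)` for a matrix, `sum(counts)` for a vector.
#' @return FPKM values with the same shape as `counts`.
#' @examples
#' compute_fpkm(100, 1000, 1e6)  # 100
#' @export
compute_fpkm <- function(counts, lengths_bp, library_sizes = NULL) {
  if (any(counts < 0)) stop("compute_fpkm: counts must be non-negative")
  if (any(lengths_bp <= 0)) stop("compute_fpkm: gene lengths must be positive")
  if (is.matrix(counts)) {
    if (is.null(library_sizes)) library_sizes <- colSums(counts)
    if (any(library_sizes <= 0)) stop("compute_fpkm: zero library size")
    sweep(counts, 2, library_sizes, "/") * 1e9 / lengths_bp
  } else {
    if (is.null(library_sizes)) library_sizes <- sum(counts)
    if (any(library_sizes <= 0)) stop("compute_fpkm: zero library size")
    counts * 1e9 / (library_sizes * lengths_bp)
  }
}

#' Log2 counts-per-million with a prior count
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)`, the common
#' prior-damped log-CPM transform used before moderated linear modelling.
#'
#' @param counts Non-negative count matrix (genes x samples) or vector.
#' @param library_sizes Per-sample library sizes; default `colSums(counts)`.
#' @param prior_count Positive damping constant, default 0.5.
#' @return Matrix (or vector) of log2 CPM values.
#' @export
log_cpm <- function(counts, library_sizes = NULL, prior_count = 0.5) {
  if (prior_count <= 0) stop("log_cpm: prior_count must be positive")
  if (any(counts < 0)) stop("log_cpm: counts must be non-negative")
  if (is.matrix(counts)) {
    if (is.null(library_sizes)) library_sizes <- colSums(counts)
    log2(sweep(counts + prior_count, 2, library_sizes + 2 * prior_count, "/") * 1e6)
  } else {
    if (is.null(library_sizes)) library_sizes <- sum(counts)
    log2((counts + prior_count) / (library_sizes + 2 * prior_count) * 1e6)
  }
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-gene two-group comparison on a log-CPM matrix. The gene-wise pooled
#' residual variance `s^2` (on `d = n1 + n2 - 2` df) is shrunk toward a
#' prior variance `s0^2` with prior weight `d0 = prior_df`:
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`, and the moderated t uses
#' `s_tilde^2` with `d + d0` degrees of freedom. With `prior_df = 0` this is
#' exactly the classical pooled two-sample t-test; with `prior_df = Inf` the
#' variance is fixed at `prior_var`. When `prior_var` is `NULL` it is
#' estimated by method of moments as the mean of the gene-wise variances.
#'
#' @param logcpm Numeric matrix, genes x samples (e.g. from [log_cpm()]).
#' @param groups Factor (or coercible) with exactly two levels; the log2
#'   fold change is mean(second level) - mean(first level), so order the
#'   levels as (control, treated).
#' @param prior_df Prior degrees of freedom `d0` (>= 0, may be `Inf`).
#' @param prior_var Prior variance `s0^2`; `NULL` estimates it from the data.
#' @return data.frame with one row per gene: `log2fc`, `t`, `df`, `p_value`,
#'   and `degenerate` (TRUE when the moderated variance is zero).
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' moderated_ttest(m, rep(c("a", "b"), each = 3), prior_df = 0)
#' @export
moderated_ttest <- function(logcpm, groups, prior_df = 4, prior_var = NULL) {
  if (!is.matrix(logcpm)) logcpm <- matrix(logcpm, nrow = 1)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("moderated_ttest: exactly two groups are required")
  if (any(table(groups) < 2L))
    stop("moderated_ttest: each group needs at least 2 samples")
  if (prior_df < 0) stop("moderated_ttest: prior_df must be >= 0")

  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(logcpm[, i1, drop = FALSE])
  m2 <- rowMeans(logcpm[, i2, drop = FALSE])
  v1 <- apply(logcpm[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(logcpm[, i2, drop = FALSE], 1, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  s0 <- if (is.null(prior_var)) mean(s2) else prior_var

  if (is.infinite(prior_df)) {
    s2_tilde <- rep(s0, length(s2))
    df_tot <- Inf
  } else {
    s2_tilde <- (prior_df * s0 + d * s2) / (prior_df + d)
    df_tot <- d + prior_df
  }

  lfc <- m2 - m1
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  degenerate <- s2_tilde == 0
  tval <- ifelse(degenerate, ifelse(lfc == 0, 0, sign(lfc) * Inf), lfc / se)
  pval <- ifelse(degenerate & lfc == 0, 1, 2 * stats::pt(-abs(tval), df_tot))
  data.frame(log2fc = lfc, t = tval, df = df_tot, p_value = pval,
             degenerate = degenerate,
             row.names = rownames(logcpm) %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`: sorted
#' ascending, `adj_(i) = min_(j>=i) p_(j) * m / j`, clipped at 1, mapped
#' back to input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR) in the input order.
#' @examples
#' bh_adjust(c(0.005, 0.5))  # 0.01 0.50
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("bh_adjust: p-values must be numeric")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-expression threshold filter
#'
#' A gene is called differentially expressed when `|log2fc| >= lfc_threshold`
#' (inclusive) and `fdr < fdr_threshold` (strict); direction follows the
#' sign of the fold change.
#'
#' @param records data.frame carrying `gene_id`, `log2fc` and `fdr`.
#' @param lfc_threshold Absolute log2 fold-change threshold, default 0.5.
#' @param fdr_threshold FDR threshold, default 0.05.
#' @return A list with character vectors `up` and `down` (disjoint).
#' @export
filter_degs <- function(records, lfc_threshold = 0.5, fdr_threshold = 0.05) {
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(records)))
    stop("filter_degs: records must have columns gene_id, log2fc, fdr")
  keep <- abs(records$log2fc) >= lfc_threshold & records$fdr < fdr_threshold
  keep[is.na(keep)] <- FALSE
  list(up = records$gene_id[keep & records$log2fc > 0],
       down = records$gene_id[keep & records$log2fc < 0])
}

#' Run the differential-expression stage on a count matrix
#'
#' Convenience wrapper chaining [log_cpm()], [moderated_ttest()],
#' [bh_adjust()], [compute_fpkm()] and [filter_degs()]. FPKM reported per
#' gene is the mean over the samples of `fpkm_group` (default treated),
#' using per-sample total counts as library sizes.
#'
#' @param counts Integer count matrix, genes x samples.
#' @param lengths_bp Gene lengths (bp), aligned with `counts` rows.
#' @param groups Two-level factor ordered (control, treated).
#' @param prior_count,prior_df,prior_var Passed to the underlying transforms.
#' @param lfc_threshold,fdr_threshold DEG thresholds, defaults 0.5 and 0.05.
#' @param fpkm_group Group level whose mean FPKM is reported.
#' @return data.frame: `gene_id`, `log2fc`, `t`, `p_value`, `fdr`, `fpkm`,
#'   `de_flag`, `direction` ("up"/"down"/"ns").
#' @export
de_analysis <- function(counts, lengths_bp, groups,
                        prior_count = 0.5, prior_df = 4, prior_var = NULL,
                        lfc_threshold = 0.5, fdr_threshold = 0.05,
                        fpkm_group = "treated") {
  groups <- as.factor(groups)
  lc <- log_cpm(counts, prior_count = prior_count)
  tt <- moderated_ttest(lc, groups, prior_df = prior_df, prior_var = prior_var)
  fdr <- bh_adjust(tt$p_value)
  fpkm_all <- compute_fpkm(counts, lengths_bp)
  sel <- if (fpkm_group %in% levels(groups)) groups == fpkm_group
         else rep(TRUE, ncol(counts))
  fpkm <- rowMeans(fpkm_all[, sel, drop = FALSE])
  res <- data.frame(
    gene_id = rownames(counts) %||% sprintf("gene_%05d", seq_len(nrow(counts))),
    log2fc = tt$log2fc, t = tt$t, p_value = tt$p_value, fdr = fdr,
    fpkm = fpkm, stringsAsFactors = FALSE
  )
  sets <- filter_degs(res, lfc_threshold, fdr_threshold)
  res$de_flag <- res$gene_id %in% c(sets$up, sets$down)
  res$direction <- ifelse(res$gene_id %in% sets$up, "up",
                          ifelse(res$gene_id %in% sets$down, "down", "ns"))
  rownames(res) <- NULL
  res
}
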