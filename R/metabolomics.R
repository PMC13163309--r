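#' Fit a two-class PLS-DA model (NIPALS)
#'
#' Partial least squares discriminant analysis for a two-class design,
#' implemented in-package with the iterative NIPALS algorithm and deflation.
#' The class response is coded +/-1 and centred; features are column-centred
#' and, by default, autoscaled to unit variance (the usual SIMCA-style
#' preprocessing; pareto and no scaling are also available). Constant
#' features are dropped with a warning. Initialization is deterministic
#' (scores started from the response), so identical inputs give identical
#' models. Components are extracted until `n_components`, each converged
#' when the score vector changes by less than 1e-10 (max 500 iterations).
#'
#' @param X Numeric matrix, features x samples.
#' @param class_labels Two-level factor (or coercible) over samples.
#' @param n_components Number of latent components, default 2; must not
#'   exceed `min(n_samples - 1, n_features)`.
#' @param scale One of "uv" (unit variance, default), "pareto", "none".
#' @return A `pls_model`: list with `weights` (p x A, unit-norm columns),
#'   `scores` (n x A), `x_loadings`, `y_loadings`, `ssy` (response sum of
#'   squares explained per component), `n_features`, `feature_ids`,
#'   `dropped` (ids of constant features), `n_components`, `scale`.
#' @export
fit_plsda <- function(X, class_labels, n_components = 2L,
                      scale = c("uv", "pareto", "none")) {
  scale <- match.arg(scale)
  if (!is.matrix(X)) stop("fit_plsda: X must be a matrix (features x samples)")
  cls <- as.factor(class_labels)
  if (nlevels(cls) != 2L) stop("fit_plsda: exactly two classes are required")
  if (length(cls) != ncol(X))
    stop("fit_plsda: class_labels must match the number of samples")

  ids <- rownames(X) %||% sprintf("feat_%04d", seq_len(nrow(X)))
  Xs <- t(X)                         # n x p
  y <- ifelse(cls == levels(cls)[2], 1, -1)
  y <- y - mean(y)
  Xs <- base::scale(Xs, center = TRUE, scale = FALSE)

  sds <- apply(Xs, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("fit_plsda: dropping ", sum(const), " constant feature(s)")
    Xs <- Xs[, !const, drop = FALSE]
    sds <- sds[!const]
    ids_kept <- ids[!const]
  } else ids_kept <- ids
  if (scale == "uv") Xs <- sweep(Xs, 2, sds, "/")
  if (scale == "pareto") Xs <- sweep(Xs, 2, sqrt(sds), "/")

  n <- nrow(Xs); p <- ncol(Xs)
  if (p == 0L) stop("fit_plsda: no non-constant features left")
  a_max <- min(n - 1L, p)
  if (n_components > a_max)
    stop(sprintf("fit_plsda: n_components (%d) exceeds the rank bound (%d)",
                 n_components, a_max))

  W <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components)
  cvec <- numeric(n_components)
  ssy <- numeric(n_components)
  Xd <- Xs
  for (a in seq_len(n_components)) {
    u <- y
    t_old <- rep(Inf, n)
    w_old <- NULL
    for (it in seq_len(500L)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      w <- w / nw
      # iterative weight estimates carry a sign indeterminacy; align with
      # the previous iterate so convergence of the scores is well defined
      if (!is.null(w_old) && sum(w * w_old) < 0) w <- -w
      w_old <- w
      t_sc <- Xd %*% w
      cc <- sum(y * t_sc) / sum(t_sc^2)
      u <- y * cc / max(cc^2, .Machine$double.eps)
      if (sqrt(sum((t_sc - t_old)^2)) < 1e-10) break
      t_old <- t_sc
    }
    pl <- crossprod(Xd, t_sc) / sum(t_sc^2)
    W[, a] <- w
    Tm[, a] <- t_sc
    P[, a] <- pl
    cvec[a] <- cc
    ssy[a] <- cc^2 * sum(t_sc^2)
    Xd <- Xd - t_sc %*% t(pl)
  }
  structure(list(weights = W, scores = Tm, x_loadings = P,
                 y_loadings = cvec, ssy = ssy, n_features = p,
                 feature_ids = ids_kept, dropped = ids[const],
                 n_components = n_components, scale = scale),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d component(s), %d feature(s), scaling '%s'\n",
              x$n_components, x$n_features, x$scale))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a ssy_a * w_aj^2 / sum_a ssy_a )` with unit-norm
#' weight vectors `w_a`, so that the mean of the squared VIP over features
#' is exactly 1 for any fitted model.
#'
#' @param model A `pls_model` from [fit_plsda()].
#' @return Named numeric vector of VIP scores, one per retained feature.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "pls_model")) stop("vip_scores: need a pls_model")
  if (sum(model$ssy) <= 0)
    stop("vip_scores: model explains no response variance")
  v <- sqrt(model$n_features *
              as.vector(model$weights^2 %*% model$ssy) / sum(model$ssy))
  stats::setNames(v, model$feature_ids)
}

#' Raw-scale fold change between classes
#'
#' `FC = mean(treated intensities) / mean(control intensities)` per feature,
#' on the raw (unlogged) scale; "treated" is the second factor level.
#'
#' @param X Positive intensity matrix, features x samples.
#' @param class_labels Two-level factor ordered (control, treated).
#' @return Named numeric vector of fold changes.
#' @export
fold_change <- function(X, class_labels) {
  cls <- as.factor(class_labels)
  if (nlevels(cls) != 2L) stop("fold_change: exactly two classes required")
  if (any(X <= 0)) stop("fold_change: intensities must be strictly positive")
  m_ctrl <- rowMeans(X[, cls == levels(cls)[1], drop = FALSE])
  m_trt <- rowMeans(X[, cls == levels(cls)[2], drop = FALSE])
  if (any(m_ctrl == 0)) stop("fold_change: zero control mean")
  stats::setNames(m_trt / m_ctrl, rownames(X))
}

#' Per-feature Welch t-test on log2 intensities
#'
#' Two-sided Welch (unequal-variance) t-test per feature, computed on log2
#' intensities by default, with BH adjustment across features. Features with
#' zero variance in both classes and equal means are flagged degenerate and
#' reported with p = 1.
#'
#' @param X Positive intensity matrix, features x samples.
#' @param class_labels Two-level factor over samples.
#' @param log_transform Test on log2 intensities (default TRUE).
#' @return data.frame `feature_id`, `p_value`, `fdr`, `degenerate`.
#' @export
univariate_test <- function(X, class_labels, log_transform = TRUE) {
  cls <- as.factor(class_labels)
  if (nlevels(cls) != 2L) stop("univariate_test: exactly two classes required")
  if (any(table(cls) < 2L))
    stop("univariate_test: each class needs at least 2 samples")
  M <- if (log_transform) log2(X) else X
  i1 <- cls == levels(cls)[1]
  i2 <- cls == levels(cls)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(M[, i1, drop = FALSE]); m2 <- rowMeans(M[, i2, drop = FALSE])
  v1 <- apply(M[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(M[, i2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 == 0
  tt <- ifelse(degenerate, 0, (m2 - m1) / sqrt(se2))
  df <- ifelse(degenerate, 1,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- ifelse(degenerate,
              ifelse(m1 == m2, 1, 0),
              2 * stats::pt(-abs(tt), df))
  data.frame(feature_id = rownames(X) %||% sprintf("feat_%04d", seq_len(nrow(X))),
             p_value = p, fdr = bh_adjust(p), degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Metabolite selection filter
#'
#' A feature is selected when VIP > `vip_min` (strict), p < `p_max`,
#' FDR < `fdr_max`, and the fold-change criterion holds. In the default
#' literal mode the effect criterion is `FC > fc_min` only (as thresholds
#' of this kind are usually printed); the two-sided option additionally
#' accepts `FC < 1 / fc_min` for down-regulated features.
#'
#' @param features data.frame with columns `vip`, `p_value`, `fdr`,
#'   `fold_change` (and any identifiers, carried through).
#' @param vip_min,p_max,fdr_max,fc_min Thresholds, defaults 1.5, 0.05,
#'   0.05, 2.0.
#' @param mode "literal" (default) or "two_sided".
#' @return The input data.frame with a logical `selected` column.
#' @export
select_metabolites <- function(features, vip_min = 1.5, p_max = 0.05,
                               fdr_max = 0.05, fc_min = 2.0,
                               mode = c("literal", "two_sided")) {
  mode <- match.arg(mode)
  need <- c("vip", "p_value", "fdr", "fold_change")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0)
    stop("select_metabolites: missing statistic column(s): ",
         paste(miss, collapse = ", "))
  if (anyNA(features[need]))
    stop("select_metabolites: statistics contain missing values")
  fc_ok <- features$fold_change > fc_min
  if (mode == "two_sided") fc_ok <- fc_ok | features$fold_change < 1 / fc_min
  features$selected <- features$vip > vip_min &
    features$p_value < p_max & features$fdr < fdr_max & fc_ok
  features
}

#' Merge redundant m/z features
#'
#' Features whose pairwise m/z difference is below `ppm_tol` parts per
#' million (relative to the lower of the two masses) and whose retention
#' times differ by at most `rt_tol_min` minutes are grouped transitively;
#' the member with the highest mean intensity represents each group.
#'
#' @param features data.frame with `feature_id`, `mz`, `rt_min` and
#'   `mean_intensity`.
#' @param ppm_tol Mass tolerance in ppm (strict <), default 5.
#' @param rt_tol_min Retention-time tolerance in minutes (inclusive),
#'   default 0.2.
#' @return The surviving (representative) rows, with a `group` id column
#'   and `n_merged` giving each group's size.
#' @export
dedup_features <- function(features, ppm_tol = 5, rt_tol_min = 0.2) {
  need <- c("feature_id", "mz", "rt_min", "mean_intensity")
  if (!all(need %in% names(features)))
    stop("dedup_features: need columns ", paste(need, collapse = ", "))
  n <- nrow(features)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        lo <- min(features$mz[i], features$mz[j])
        ppm <- abs(features$mz[i] - features$mz[j]) / lo * 1e6
        if (ppm < ppm_tol &&
            abs(features$rt_min[i] - features$rt_min[j]) <= rt_tol_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  keep <- vapply(groups, function(idx)
    idx[which.max(features$mean_intensity[idx])], integer(1))
  out <- features[keep, , drop = FALSE]
  out$group <- seq_along(keep)
  out$n_merged <- vapply(groups, length, integer(1))
  rownames(out) <- NULL
  out
}

#' Run the metabolomics stage on an intensity table
#'
#' Chains [fit_plsda()]/[vip_scores()], [univariate_test()],
#' [fold_change()], the selection filter and redundancy resolution.
#'
#' @param intensities Positive matrix, features x samples.
#' @param features data.frame with `feature_id`, `mz`, `rt_min`.
#' @param class_labels Two-level factor ordered (control, treated).
#' @param n_components PLS components, default 2.
#' @param dedup Apply [dedup_features()] before filtering (default TRUE).
#' @param ... Thresholds forwarded to [select_metabolites()].
#' @return data.frame per (deduplicated) feature with all four statistics
#'   and the `selected` flag.
#' @export
metab_analysis <- function(intensities, features, class_labels,
                           n_components = 2L, dedup = TRUE, ...) {
  stopifnot(nrow(intensities) == nrow(features))
  tab <- features
  tab$mean_intensity <- rowMeans(intensities)
  if (dedup) {
    tab <- dedup_features(tab)
    intensities <- intensities[match(tab$feature_id, features$feature_id), ,
                               drop = FALSE]
  }
  model <- fit_plsda(log2(intensities), class_labels,
                     n_components = n_components)
  vip <- vip_scores(model)
  uni <- univariate_test(intensities, class_labels)
  tab$vip <- unname(vip[tab$feature_id])
  tab$p_value <- uni$p_value
  tab$fdr <- uni$fdr
  tab$fold_change <- unname(fold_change(intensities, class_labels))
  select_metabolites(tab, ...)
}
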