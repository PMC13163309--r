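#' Percent cell viability from plate absorbances
#'
#' `100 * (A_sample - A_blank) / (A_control - A_blank)`. Values are not
#' clipped: readings above the control or below the blank legitimately give
#' viabilities above 100% or below 0%, and clipping before curve fitting
#' would bias the lower asymptote.
#'
#' @param a_sample Absorbance of treated wells (OD450).
#' @param a_control Absorbance of untreated control wells.
#' @param a_blank Absorbance of cell-free blank wells.
#' @return Viability in percent (vectorized over `a_sample`).
#' @examples
#' viability_percent(0.6, 1.1, 0.1)  # 50
#' @export
viability_percent <- function(a_sample, a_control, a_blank) {
  if (any(a_control == a_blank))
    stop("viability_percent: control and blank absorbances are equal")
  100 * (a_sample - a_blank) / (a_control - a_blank)
}

#' Per-well viabilities for a plate table
#'
#' Converts sample-well absorbances to viability percentages using the
#' mean control and blank absorbances of the same compound and biological
#' replicate.
#'
#' @param plate data.frame as produced by [simulate_plate()] (columns
#'   compound, conc_uM, bio_rep, tech_rep, well_type, absorbance).
#' @return The sample rows with an added `viability` column.
#' @export
plate_viability <- function(plate) {
  need <- c("compound", "conc_uM", "bio_rep", "well_type", "absorbance")
  if (!all(need %in% names(plate)))
    stop("plate_viability: plate needs columns ", paste(need, collapse = ", "))
  out <- list()
  for (cmp in unique(plate$compound)) {
    for (b in unique(plate$bio_rep[plate$compound == cmp])) {
      sub <- plate[plate$compound == cmp & plate$bio_rep == b, , drop = FALSE]
      a_ctrl <- mean(sub$absorbance[sub$well_type == "control"])
      a_blank <- mean(sub$absorbance[sub$well_type == "blank"])
      if (!is.finite(a_ctrl) || !is.finite(a_blank))
        stop("plate_viability: missing control or blank wells for ",
             cmp, " / bio_rep ", b)
      s <- sub[sub$well_type == "sample", , drop = FALSE]
      s$viability <- viability_percent(s$absorbance, a_ctrl, a_blank)
      out[[length(out) + 1L]] <- s
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average technical replicates within biological replicates
#'
#' Technical-replicate viabilities are averaged within each biological
#' replicate before curve fitting; biological replicates are kept separate.
#' The mean is invariant to well ordering.
#'
#' @param wells data.frame with columns `compound`, `conc_uM`, `bio_rep`,
#'   `viability` (e.g. from [plate_viability()]).
#' @return data.frame, one row per (compound, conc_uM, bio_rep) with the
#'   mean `viability`.
#' @export
aggregate_replicates <- function(wells) {
  need <- c("compound", "conc_uM", "bio_rep", "viability")
  if (!all(need %in% names(wells)))
    stop("aggregate_replicates: need columns ", paste(need, collapse = ", "))
  if (nrow(wells) == 0L) stop("aggregate_replicates: empty input")
  agg <- stats::aggregate(viability ~ compound + conc_uM + bio_rep,
                          data = wells, FUN = mean)
  agg[order(agg$compound, agg$conc_uM, agg$bio_rep), , drop = FALSE]
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`
#' with `log10(ic50)` as the free concentration parameter for conditioning.
#' Starting values take `top`/`bottom` from the data extremes, the IC50
#' start from the concentration nearest 50% response (and the geometric
#' mean of the tested range), and hill slopes of both signs; 8 starts are
#' tried with Levenberg-Marquardt and the converged fit with the lowest
#' residual sum of squares is kept.
#'
#' @param concentrations Positive concentrations (uM); at least 4 distinct
#'   values are required.
#' @param viabilities Viability percentages, same length.
#' @return A `dose_response_fit`: list with `bottom`, `top`, `hill`, `ic50`
#'   (uM), `r_squared`, `sse`, `n`, `converged`, `undetermined`. Constant
#'   input returns `undetermined = TRUE` with `ic50 = NA`; if no start
#'   converges an error carrying the per-start diagnostics is thrown.
#' @examples
#' x <- c(0.03, 1, 3, 10, 30, 100)
#' y <- 0 + (100 - 0) / (1 + (x / 1)^1)
#' fit_4pl(x, y)$ic50
#' @export
fit_4pl <- function(concentrations, viabilities) {
  x <- as.numeric(concentrations)
  y <- as.numeric(viabilities)
  if (length(x) != length(y)) stop("fit_4pl: lengths differ")
  if (any(x <= 0)) stop("fit_4pl: concentrations must be positive")
  if (length(unique(x)) < 4L)
    stop("fit_4pl: at least 4 distinct concentrations are required")

  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    warning("fit_4pl: constant viability; IC50 undetermined")
    return(structure(list(bottom = mean(y), top = mean(y), hill = 0,
                          ic50 = NA_real_, r_squared = NA_real_,
                          sse = 0, n = length(y), converged = FALSE,
                          undetermined = TRUE),
                     class = "dose_response_fit"))
  }

  bot0 <- min(y); top0 <- max(y)
  half <- (top0 + bot0) / 2
  x50 <- x[which.min(abs(y - half))]
  xgeo <- exp(mean(log(range(x))))
  starts <- expand.grid(l10 = log10(unique(c(x50, xgeo))),
                        hill = c(1, -1, 2, -2))
  fits <- list()
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (x / 10^l10)^hill),
        start = list(bottom = bot0, top = top0,
                     hill = starts$hill[i], l10 = starts$l10[i]),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) e
    )
    fits[[i]] <- fit
  }
  ok <- vapply(fits, function(f) inherits(f, "nls"), logical(1))
  if (!any(ok)) {
    msgs <- vapply(fits, conditionMessage, "")
    stop("fit_4pl: no start converged; diagnostics: ",
         paste(unique(msgs), collapse = " | "))
  }
  sse <- vapply(fits[ok], function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[ok][[which.min(sse)]]
  cf <- stats::coef(best)
  # the 4PL has an exact (bottom, top, hill) <-> (top, bottom, -hill)
  # symmetry; canonicalize so that `top` is the zero-dose asymptote
  if (cf["bottom"] > cf["top"]) {
    cf[c("bottom", "top")] <- cf[c("top", "bottom")]
    cf["hill"] <- -cf["hill"]
  }
  structure(list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                 hill = unname(cf["hill"]), ic50 = unname(10^cf["l10"]),
                 r_squared = 1 - min(sse) / sstot,
                 sse = min(sse), n = length(y), converged = TRUE,
                 undetermined = FALSE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$undetermined) {
    cat("4PL fit: undetermined (constant response)\n")
  } else {
    cat(sprintf(
      "4PL fit: IC50 = %.4g uM (bottom %.1f, top %.1f, hill %.2f, r2 %.4f)\n",
      x$ic50, x$bottom, x$top, x$hill, x$r_squared))
  }
  invisible(x)
}

#' Fit dose-response curves for every compound on a plate
#'
#' @param plate Plate table (see [simulate_plate()]).
#' @return data.frame, one row per compound: `compound`, `bottom`, `top`,
#'   `hill`, `ic50_uM`, `r2`.
#' @export
fit_plate <- function(plate) {
  vi <- aggregate_replicates(plate_viability(plate))
  res <- lapply(split(vi, vi$compound), function(d) {
    f <- fit_4pl(d$conc_uM, d$viability)
    data.frame(compound = d$compound[1], bottom = f$bottom, top = f$top,
               hill = f$hill, ic50_uM = f$ic50, r2 = f$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
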