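#' Read a docking result table
#'
#' Expects a delimited file with header columns `compound`, `compound_id`,
#' `formula`, `mz`, `rt_min`, `target`, `docking_score`, `dg_bind`
#' (kcal/mol, MM-GBSA). Typographic minus signs are normalized and a
#' `compound_norm` column is added.
#'
#' @param path File path.
#' @param sep Field separator, default tab.
#' @return data.frame of docking records.
#' @export
read_docking_table <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8", quote = "")
  need <- c("compound", "target", "docking_score", "dg_bind")
  if (!all(need %in% names(df)))
    stop("read_docking_table: need columns ", paste(need, collapse = ", "))
  for (cl in c("mz", "rt_min", "docking_score", "dg_bind"))
    if (cl %in% names(df)) df[[cl]] <- as.numeric(.ascii_minus(df[[cl]]))
  df$compound_norm <- normalize_compound_names(df$compound)
  df
}

.check_docking <- function(records) {
  need <- c("compound", "target", "docking_score", "dg_bind")
  if (!all(need %in% names(records)))
    stop("docking records need columns ", paste(need, collapse = ", "))
  if (!all(is.finite(records$docking_score)) || !all(is.finite(records$dg_bind)))
    stop("docking scores and binding energies must be finite")
  records
}

#' Top-k ligands for one target by docking score
#'
#' More negative docking scores are better; the primary ranking key is the
#' docking score ascending, with ties broken by binding free energy
#' ascending, then compound name. Ranking ligands by binding free energy
#' instead would give a different order; docking score is the key under
#' which published prioritized triples are consistently the top 3.
#'
#' @param records Docking-record data.frame (see [read_docking_table()]).
#' @param target Target protein label.
#' @param k Number of ligands to return, default 3.
#' @return data.frame of the top-k records for the target with a `rank`
#'   column; zero rows (with a warning) for an unknown target.
#' @export
rank_ligands <- function(records, target, k = 3L) {
  records <- .check_docking(records)
  sub <- records[records$target == target, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("rank_ligands: no records for target '", target, "'")
    sub$rank <- integer(0)
    return(sub)
  }
  ord <- order(sub$docking_score, sub$dg_bind, sub$compound)
  sub <- sub[ord, , drop = FALSE]
  sub <- sub[seq_len(min(k, nrow(sub))), , drop = FALSE]
  sub$rank <- seq_len(nrow(sub))
  rownames(sub) <- NULL
  sub
}

#' Cross-target ligand profiles
#'
#' Builds one profile per compound appearing in at least one per-target
#' top-k set: the targets where it is prioritized, with its docking score
#' and binding free energy for each.
#'
#' @param records Docking-record data.frame.
#' @param k Top-k membership per target, default 3.
#' @param targets Targets to profile; default all in `records`.
#' @return A `ligand_profiles` object: named list (by normalized compound
#'   name), each with `compound`, `targets_hit` and `best_scores`
#'   (data.frame target, docking_score, dg_bind).
#' @export
multitarget_profile <- function(records, k = 3L, targets = NULL) {
  records <- .check_docking(records)
  if (!"compound_norm" %in% names(records))
    records$compound_norm <- normalize_compound_names(records$compound)
  if (is.null(targets)) targets <- unique(records$target)
  tops <- do.call(rbind, lapply(targets, rank_ligands, records = records, k = k))
  profs <- lapply(split(tops, tops$compound_norm), function(d) {
    list(compound = d$compound[1],
         targets_hit = unique(d$target),
         best_scores = data.frame(target = d$target,
                                  docking_score = d$docking_score,
                                  dg_bind = d$dg_bind,
                                  stringsAsFactors = FALSE))
  })
  structure(profs, class = "ligand_profiles")
}

#' @export
print.ligand_profiles <- function(x, ...) {
  cat("ligand profiles (", length(x), " compound(s)):\n", sep = "")
  for (p in x)
    cat(sprintf("  %s -> %s\n", p$compound,
                paste(p$targets_hit, collapse = ", ")))
  invisible(x)
}

#' Select assay candidates from ligand profiles
#'
#' For each target, among its top-k prioritized ligands that appear on the
#' externally supplied molecular-dynamics pass list, picks the one with the
#' best (most negative) binding free energy; the per-target picks are
#' returned as a deduplicated union. Binding energies default to the
#' docking table's `dg_bind` column, but an MD-stage MM-GBSA table can be
#' supplied via `dg_override` (columns `compound`, `target`, `dg_bind_md`),
#' since docking-stage and MD-stage energy estimates for the same complex
#' routinely differ. With an empty or missing MD-pass list, selection falls
#' back to the docking rank-1 ligand with a warning.
#'
#' @param records Docking-record data.frame.
#' @param md_pass Named list (by target) of compounds that passed MD
#'   stability review, or NULL.
#' @param k Top-k membership per target, default 3.
#' @param dg_override Optional data.frame of MD-stage binding energies.
#' @param targets Targets to select for; default all in `records`.
#' @return Character vector of unique compound names (display spelling),
#'   one pick per target before deduplication.
#' @export
select_assay_candidates <- function(records, md_pass = NULL, k = 3L,
                                    dg_override = NULL, targets = NULL) {
  records <- .check_docking(records)
  if (!"compound_norm" %in% names(records))
    records$compound_norm <- normalize_compound_names(records$compound)
  if (is.null(targets)) targets <- unique(records$target)
  if (!is.null(dg_override)) {
    if (!all(c("compound", "target", "dg_bind_md") %in% names(dg_override)))
      stop("select_assay_candidates: dg_override needs compound, target, dg_bind_md")
    dg_override$compound_norm <-
      dg_override$compound_norm %||% normalize_compound_names(dg_override$compound)
  }
  picks <- character(0)
  for (tg in targets) {
    top <- rank_ligands(records, tg, k)
    cand <- top
    passed <- md_pass[[tg]]
    if (is.null(passed) || length(passed) == 0L) {
      warning("select_assay_candidates: empty MD-pass list for '", tg,
              "'; falling back to docking rank 1")
      cand <- top[1, , drop = FALSE]
    } else {
      cand <- top[top$compound_norm %in% normalize_compound_names(passed), ,
                  drop = FALSE]
      if (nrow(cand) == 0L) {
        warning("select_assay_candidates: MD-pass list matches no top-", k,
                " ligand for '", tg, "'; falling back to docking rank 1")
        cand <- top[1, , drop = FALSE]
      }
    }
    dg <- cand$dg_bind
    if (!is.null(dg_override)) {
      ov <- dg_override[dg_override$target == tg, , drop = FALSE]
      idx <- match(cand$compound_norm, ov$compound_norm)
      dg <- ifelse(is.na(idx), dg, ov$dg_bind_md[idx])
    }
    picks <- c(picks, cand$compound[which.min(dg)])
  }
  unique(picks)
}
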