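#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic pipeline inputs into one validated
#' object. The defaults are the study conditions exercised throughout the
#' test suite: a desk-scale two-condition RNA-seq experiment (2000 genes,
#' three biological replicates per condition), a two-class metabolite feature
#' table, an Erdos-Renyi interaction graph with planted hubs, and a CCK-8
#' style dose-response plate at six concentrations.
#'
#' @param seed Integer seed; every generator is a pure function of the config,
#'   so the same seed yields bit-identical output.
#' @param n_genes Number of genes to simulate.
#' @param n_per_group Biological replicates per condition (control / treated).
#' @param frac_de Fraction of genes carrying a planted expression shift.
#' @param lfc_magnitude Absolute log2 fold change of planted genes.
#' @param nb_dispersion Shared negative-binomial dispersion (1/size).
#' @param n_features_metab Number of metabolite features.
#' @param n_metab_per_group Samples per class in the metabolite table.
#' @param frac_discriminant Fraction of features with a planted class effect.
#' @param disc_fold Multiplicative (raw-scale) planted effect; must exceed 2
#'   for the downstream fold-change filter to be recoverable.
#' @param metab_sdlog Log-normal noise sd (natural-log scale) of intensities.
#' @param graph_n_nodes,graph_edge_prob Erdos-Renyi background graph size and
#'   edge probability.
#' @param planted_hub_count Number of planted high-degree hub nodes.
#' @param hub_degree_factor Hub wiring probability as a multiple of
#'   `graph_edge_prob`; must be at least 2 so hubs sit at twice the expected
#'   background degree or more.
#' @param plate_true_params Named list, one entry per compound, each a numeric
#'   vector with elements `bottom`, `top`, `hill`, `ic50` (viability %, %,
#'   dimensionless, uM) defining the true four-parameter-logistic curve.
#' @param plate_concentrations Assay concentrations in uM.
#' @param plate_noise_pct Gaussian noise sd on viability, in percentage points.
#' @param n_bio_rep,n_tech_rep Biological and technical replicates per
#'   concentration on the plate.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 500)
#' cfg$frac_de
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_per_group = 3L,
                       frac_de = 0.05,
                       lfc_magnitude = 1.5,
                       nb_dispersion = 0.02,
                       n_features_metab = 300L,
                       n_metab_per_group = 6L,
                       frac_discriminant = 0.05,
                       disc_fold = 3.0,
                       metab_sdlog = 0.3,
                       graph_n_nodes = 150L,
                       graph_edge_prob = 0.05,
                       planted_hub_count = 5L,
                       hub_degree_factor = 6,
                       plate_true_params = list(
                         compound_A = c(bottom = 0, top = 100, hill = 1, ic50 = 1)
                       ),
                       plate_concentrations = c(0.03, 1, 3, 10, 30, 100),
                       plate_noise_pct = 3,
                       n_bio_rep = 2L,
                       n_tech_rep = 3L) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_per_group = as.integer(n_per_group), frac_de = frac_de,
    lfc_magnitude = lfc_magnitude, nb_dispersion = nb_dispersion,
    n_features_metab = as.integer(n_features_metab),
    n_metab_per_group = as.integer(n_metab_per_group),
    frac_discriminant = frac_discriminant, disc_fold = disc_fold,
    metab_sdlog = metab_sdlog, graph_n_nodes = as.integer(graph_n_nodes),
    graph_edge_prob = graph_edge_prob,
    planted_hub_count = as.integer(planted_hub_count),
    hub_degree_factor = hub_degree_factor,
    plate_true_params = plate_true_params,
    plate_concentrations = plate_concentrations,
    plate_noise_pct = plate_noise_pct,
    n_bio_rep = as.integer(n_bio_rep), n_tech_rep = as.integer(n_tech_rep)
  )
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.cfg_stop <- function(field, why) {
  stop(sprintf("invalid sim_config field '%s': %s", field, why), call. = FALSE)
}

.validate_sim_config <- function(cfg) {
  counts <- c("n_genes", "n_per_group", "n_features_metab",
              "n_metab_per_group", "graph_n_nodes", "n_bio_rep", "n_tech_rep")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      .cfg_stop(f, "must be a count >= 1")
  }
  if (cfg$planted_hub_count < 0L) .cfg_stop("planted_hub_count", "must be >= 0")
  if (cfg$planted_hub_count >= cfg$graph_n_nodes)
    .cfg_stop("planted_hub_count", "must be smaller than graph_n_nodes")
  for (f in c("frac_de", "frac_discriminant", "graph_edge_prob")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      .cfg_stop(f, "must be a fraction in [0, 1]")
  }
  if (cfg$nb_dispersion <= 0) .cfg_stop("nb_dispersion", "must be positive")
  if (cfg$metab_sdlog < 0) .cfg_stop("metab_sdlog", "must be non-negative")
  if (cfg$hub_degree_factor < 2)
    .cfg_stop("hub_degree_factor", "hubs must be wired at >= 2x background")
  if (any(cfg$plate_concentrations <= 0))
    .cfg_stop("plate_concentrations", "concentrations must be positive")
  if (cfg$plate_noise_pct < 0) .cfg_stop("plate_noise_pct", "must be >= 0")
  for (nm in names(cfg$plate_true_params)) {
    p <- cfg$plate_true_params[[nm]]
    if (!all(c("bottom", "top", "hill", "ic50") %in% names(p)))
      .cfg_stop("plate_true_params",
                sprintf("entry '%s' must name bottom, top, hill, ic50", nm))
    if (p[["ic50"]] <= 0)
      .cfg_stop("plate_true_params", sprintf("entry '%s': ic50 must be > 0", nm))
  }
  invisible(cfg)
}

#' Simulate a two-condition RNA-seq count matrix with planted DE genes
#'
#' Counts are negative binomial with gene-wise baseline means drawn
#' log-normally across genes and a single shared dispersion. Exactly
#' `round(frac_de * n_genes)` genes carry a mean shift of
#' `+/- lfc_magnitude` (log2) in the treated group; shift direction is
#' random per gene and recorded in the truth labels.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `counts` (integer matrix, genes x samples),
#'   `lengths` (named positive integer vector, bp), `groups` (factor,
#'   levels control/treated) and `truth` (list: `de_gene_ids`, `true_lfc`).
#' @examples
#' sim <- simulate_counts(sim_config(seed = 7, n_genes = 200))
#' dim(sim$counts)
#' length(sim$truth$de_gene_ids)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$n_genes
  n <- config$n_per_group
  gene_ids <- sprintf("gene_%05d", seq_len(g))
  base_mu <- stats::rlnorm(g, meanlog = 5, sdlog = 1.2)

  n_de <- round(config$frac_de * g)
  true_lfc <- stats::setNames(numeric(g), gene_ids)
  de_idx <- if (n_de > 0) sample.int(g, n_de) else integer(0)
  if (n_de > 0) {
    true_lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      config$lfc_magnitude
  }

  mu_ctrl <- base_mu
  mu_trt <- base_mu * 2^true_lfc
  size <- 1 / config$nb_dispersion
  counts <- cbind(
    matrix(stats::rnbinom(g * n, mu = rep(mu_ctrl, n), size = size), nrow = g),
    matrix(stats::rnbinom(g * n, mu = rep(mu_trt, n), size = size), nrow = g)
  )
  dimnames(counts) <- list(gene_ids,
                           c(paste0("control_", seq_len(n)),
                             paste0("treated_", seq_len(n))))
  lengths <- stats::setNames(sample(200:10000, g, replace = TRUE), gene_ids)
  groups <- factor(rep(c("control", "treated"), each = n),
                   levels = c("control", "treated"))
  list(counts = counts, lengths = lengths, groups = groups,
       truth = list(de_gene_ids = gene_ids[sort(de_idx)],
                    true_lfc = true_lfc))
}

#' Simulate a two-class metabolite intensity table
#'
#' Intensities are log-normal; the planted class effect is multiplicative on
#' the raw scale (`disc_fold` in the treated class) so that the raw-scale
#' fold change of discriminant features is directly interpretable.
#'
#' @param config A [sim_config()] object.
#' @return A list with `intensities` (features x samples, strictly positive),
#'   `features` (data.frame: feature_id, mz, rt_min), `classes` (factor,
#'   control/treated) and `truth` (list: `discriminant_feature_ids`,
#'   `true_fold`).
#' @export
simulate_metabolite_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$n_features_metab
  n <- config$n_metab_per_group
  ids <- sprintf("feat_%04d", seq_len(p))
  base <- stats::rlnorm(p, meanlog = 11, sdlog = 1)

  n_disc <- round(config$frac_discriminant * p)
  fold <- stats::setNames(rep(1, p), ids)
  disc_idx <- if (n_disc > 0) sample.int(p, n_disc) else integer(0)
  fold[disc_idx] <- config$disc_fold

  noise <- function() stats::rlnorm(p * n, meanlog = 0, sdlog = config$metab_sdlog)
  ctrl <- matrix(rep(base, n) * noise(), nrow = p)
  trt <- matrix(rep(base * fold, n) * noise(), nrow = p)
  x <- cbind(ctrl, trt)
  dimnames(x) <- list(ids, c(paste0("control_", seq_len(n)),
                             paste0("treated_", seq_len(n))))
  features <- data.frame(
    feature_id = ids,
    mz = stats::runif(p, 100, 800),
    rt_min = stats::runif(p, 0.5, 12),
    stringsAsFactors = FALSE
  )
  classes <- factor(rep(c("control", "treated"), each = n),
                    levels = c("control", "treated"))
  list(intensities = x, features = features, classes = classes,
       truth = list(discriminant_feature_ids = ids[sort(disc_idx)],
                    true_fold = fold))
}

#' Simulate a weighted interaction edge list with planted hubs
#'
#' Background edges follow an Erdos-Renyi model; the planted hubs are wired
#' to every other node with probability `hub_degree_factor * graph_edge_prob`
#' (capped at 1), placing their expected degree at least twice the background.
#' Edge weights are uniform on \[0.4, 1\] so that a 0.700 confidence
#' threshold retains roughly half of the edges.
#'
#' @param config A [sim_config()] object.
#' @return A list with `edges` (data.frame: node_a, node_b, combined_score)
#'   and `truth` (list: `hub_node_ids`).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$graph_n_nodes < 2)
    .cfg_stop("graph_n_nodes", "must be >= 2")
  set.seed(config$seed)
  nn <- config$graph_n_nodes
  ids <- sprintf("node_%03d", seq_len(nn))
  hubs <- if (config$planted_hub_count > 0)
    sort(sample.int(nn, config$planted_hub_count)) else integer(0)

  pairs <- utils::combn(nn, 2)
  is_hub_pair <- (pairs[1, ] %in% hubs) | (pairs[2, ] %in% hubs)
  p_edge <- ifelse(is_hub_pair,
                   pmin(1, config$hub_degree_factor * config$graph_edge_prob),
                   config$graph_edge_prob)
  keep <- stats::runif(ncol(pairs)) < p_edge
  m <- sum(keep)
  edges <- data.frame(
    node_a = ids[pairs[1, keep]],
    node_b = ids[pairs[2, keep]],
    combined_score = if (m > 0) stats::runif(m, 0.4, 1.0) else numeric(0),
    stringsAsFactors = FALSE
  )
  list(edges = edges, truth = list(hub_node_ids = ids[hubs]))
}

# 4PL mean curve; hill > 0 gives a descending inhibitor-vs-response shape.
.four_pl <- function(x, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Simulate a CCK-8 style absorbance plate
#'
#' For each compound, viability at each concentration follows the true
#' four-parameter-logistic curve in the config plus Gaussian noise
#' (`plate_noise_pct` percentage points), then is mapped to OD450 absorbance
#' between a blank level (0.10) and an untreated-control level (1.10).
#' Control and blank wells are emitted per biological replicate.
#'
#' @param config A [sim_config()] object.
#' @return A list with `plate` (data.frame: compound, conc_uM, bio_rep,
#'   tech_rep, well_type in sample/control/blank, absorbance) and `truth`
#'   (list: `true_ic50`, named per compound, uM).
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  blank_od <- 0.10
  ctrl_od <- 1.10
  noise_od <- (ctrl_od - blank_od) * config$plate_noise_pct / 100

  rows <- list()
  for (cmp in names(config$plate_true_params)) {
    pars <- config$plate_true_params[[cmp]]
    for (b in seq_len(config$n_bio_rep)) {
      for (conc in config$plate_concentrations) {
        v <- .four_pl(conc, pars[["bottom"]], pars[["top"]],
                      pars[["hill"]], pars[["ic50"]])
        od <- blank_od + (ctrl_od - blank_od) * v / 100 +
          stats::rnorm(config$n_tech_rep, 0, noise_od)
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cmp, conc_uM = conc, bio_rep = b,
          tech_rep = seq_len(config$n_tech_rep), well_type = "sample",
          absorbance = od, stringsAsFactors = FALSE
        )
      }
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp, conc_uM = 0, bio_rep = b,
        tech_rep = seq_len(config$n_tech_rep), well_type = "control",
        absorbance = ctrl_od + stats::rnorm(config$n_tech_rep, 0, noise_od),
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp, conc_uM = 0, bio_rep = b,
        tech_rep = seq_len(config$n_tech_rep), well_type = "blank",
        absorbance = blank_od + stats::rnorm(config$n_tech_rep, 0, noise_od),
        stringsAsFactors = FALSE
      )
    }
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  true_ic50 <- vapply(config$plate_true_params, function(p) p[["ic50"]],
                      numeric(1))
  list(plate = plate, truth = list(true_ic50 = true_ic50))
}
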