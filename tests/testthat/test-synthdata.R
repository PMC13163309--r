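test_that("generators are pure functions of the config (seed determinism)", {
  cfg <- sim_config(seed = 42, n_genes = 300, n_features_metab = 80,
                    graph_n_nodes = 60)
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  expect_identical(simulate_metabolite_table(cfg),
                   simulate_metabolite_table(cfg))
  expect_identical(simulate_network(cfg), simulate_network(cfg))
  expect_identical(simulate_plate(cfg), simulate_plate(cfg))
  # a different seed changes the data
  cfg2 <- sim_config(seed = 43, n_genes = 300)
  expect_false(identical(simulate_counts(cfg)$counts,
                         simulate_counts(cfg2)$counts))
})

test_that("count simulation plants exactly the requested signal", {
  cfg <- sim_config(seed = 5, n_genes = 400, frac_de = 0.1)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == floor(sim$counts)))
  expect_true(all(sim$lengths > 0))
  expect_length(sim$truth$de_gene_ids, round(0.1 * 400))
  expect_true(all(sim$truth$de_gene_ids %in% rownames(sim$counts)))
  # planted direction: generated group means differ as declared
  planted <- sim$truth$de_gene_ids
  lfc_hat <- rowMeans(log2(sim$counts[planted, 4:6] + 0.5)) -
    rowMeans(log2(sim$counts[planted, 1:3] + 0.5))
  expect_true(all(sign(lfc_hat) == sign(sim$truth$true_lfc[planted])))
  # no planted signal when frac_de = 0
  sim0 <- simulate_counts(sim_config(seed = 5, n_genes = 400, frac_de = 0))
  expect_length(sim0$truth$de_gene_ids, 0)
  expect_true(all(sim0$truth$true_lfc == 0))
})

test_that("metabolite simulation is positive with interpretable raw-scale effects", {
  cfg <- sim_config(seed = 9)
  mt <- simulate_metabolite_table(cfg)
  expect_true(all(mt$intensities > 0))
  disc <- mt$truth$discriminant_feature_ids
  fc <- fold_change(mt$intensities, mt$classes)
  expect_true(all(fc[disc] > 2))  # group mean ratio above 2 on the raw scale
  mt0 <- simulate_metabolite_table(sim_config(seed = 9, frac_discriminant = 0))
  expect_length(mt0$truth$discriminant_feature_ids, 0)
  expect_true(all(mt0$truth$true_fold == 1))
})

test_that("network simulation produces valid weighted edge lists", {
  nw <- simulate_network(sim_config(seed = 3))
  expect_true(all(nw$edges$combined_score >= 0 &
                    nw$edges$combined_score <= 1))
  expect_true(all(nw$edges$node_a != nw$edges$node_b))
  empty <- simulate_network(sim_config(seed = 3, graph_edge_prob = 0,
                                       planted_hub_count = 0))
  expect_identical(nrow(empty$edges), 0L)
  expect_error(sim_config(graph_edge_prob = 1.5), "graph_edge_prob")
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_de = -0.1), "frac_de")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(plate_concentrations = c(0, 1)),
               "plate_concentrations")
  expect_error(sim_config(plate_true_params = list(a = c(bottom = 0, top = 1,
                                                         hill = 1, ic50 = -1))),
               "ic50")
})

test_that("noiseless plates lie exactly on the true logistic curve", {
  cfg <- sim_config(seed = 2, plate_noise_pct = 0,
                    plate_true_params = list(
                      d1 = c(bottom = 10, top = 90, hill = 1.5, ic50 = 4)))
  pl <- simulate_plate(cfg)
  vi <- plate_viability(pl$plate)
  expected <- 10 + (90 - 10) / (1 + (vi$conc_uM / 4)^1.5)
  expect_equal(vi$viability, expected, tolerance = 1e-12)
  # blanks sit below controls
  expect_lt(mean(pl$plate$absorbance[pl$plate$well_type == "blank"]),
            mean(pl$plate$absorbance[pl$plate$well_type == "control"]))
})

test_that("packaged fixtures load with verified content", {
  t1 <- load_fixture("table1")
  expect_identical(nrow(t1), 20L)
  expect_identical(t1$gene[1], "APP")
  expect_equal(t1$p_adjust[1], 1.20e-8)
  expect_equal(t1$fpkm[1], 50.00)
  expect_equal(t1$relevance[1], 1.0)

  t2 <- load_fixture("table2")
  expect_identical(nrow(t2), 50L)
  lact <- t2[t2$target == "MAOB" & t2$compound == "Lactol", ]
  expect_equal(lact$docking_score, -9.698)
  expect_equal(lact$dg_bind, -33.86)
  expect_identical(sort(unique(t2$target)),
                   sort(c("MAOB", "BRAF", "BACE1", "GSK3β", "PARP1")))

  md <- load_fixture("md_energies")
  expect_identical(nrow(md), 15L)
  expect_error(load_fixture("table3"))
})

test_that("planted DE genes are recovered by the expression stage", {
  cfg <- sim_config(seed = 7, n_genes = 2000, frac_de = 0.05,
                    lfc_magnitude = 1.5)
  sim <- simulate_counts(cfg)
  de <- de_analysis(sim$counts, sim$lengths, sim$groups)
  sets <- filter_degs(de)
  called <- c(sets$up, sets$down)
  truth <- sim$truth$de_gene_ids
  expect_gte(mean(truth %in% called), 0.7)
  expect_lte(mean(!(called %in% truth)), 0.10)
})
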