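test_that("paired expression generation is deterministic and well-shaped", {
  cfg <- tiny_config(seed = 4)
  g1 <- generate_paired_expression(cfg)
  g2 <- generate_paired_expression(cfg)
  expect_identical(g1, g2)
  expect_equal(dim(g1$expr_a), c(120L, 48L))
  expect_equal(ncol(g1$expr_b), 48L)
  expect_equal(nrow(g1$expr_b), round(0.9 * 120))
  expect_identical(colnames(g1$expr_a), colnames(g1$expr_b))
  expect_length(unlist(g1$truth$modules), 90L)
  expect_length(g1$truth$clusters, 48L)
  # panel overlap 1 means identical gene panels
  gfull <- generate_paired_expression(tiny_config(seed = 4,
                                                  panel_overlap = 1))
  expect_identical(rownames(gfull$expr_a), rownames(gfull$expr_b))
})

test_that("zero module shift removes recoverable cluster structure", {
  cfg <- tiny_config(seed = 6, module_shift = 0)
  g <- generate_paired_expression(cfg)
  cc <- consensus_cluster(g$expr_a, axis = "columns",
                          k_range = cfg$n_clusters, n_iterations = 15,
                          seed = 1)
  ari <- mclust::adjustedRandIndex(
    cc$assignments_per_k[, 1], g$truth$clusters[cc$item_ids])
  expect_lt(abs(ari), 0.1)
})

test_that("interaction graph mirrors the planted communities", {
  g <- generate_paired_expression(tiny_config(seed = 8))
  gr <- generate_interaction_graph(g$truth, within_score = 0.9,
                                   within_density = 1, cross_rate = 0)
  # cross_rate 0 with full density: disjoint union of module cliques
  mod_of <- rep(names(g$truth$modules),
                vapply(g$truth$modules, length, integer(1)))
  names(mod_of) <- unlist(g$truth$modules)
  expect_true(all(mod_of[gr$gene_a] == mod_of[gr$gene_b]))
  expect_true(all(gr$score == 0.9))
  n_clique_edges <- sum(vapply(g$truth$modules, function(m)
    choose(length(m), 2), numeric(1)))
  expect_equal(nrow(gr), n_clique_edges)
  # determinism
  expect_identical(gr, generate_interaction_graph(g$truth, within_score = 0.9,
                                                  within_density = 1,
                                                  cross_rate = 0))
  # scores below the strong-edge threshold leave nothing for the filter
  gr_weak <- generate_interaction_graph(g$truth, within_score = 0.6,
                                        within_density = 1, cross_rate = 0)
  mod1 <- structure(list(module_id = "module_1",
                         gene_ids = g$truth$modules[[1]]),
                    class = "GeneModule")
  rep <- filter_by_network(mod1, gr_weak, g$expr_a)
  expect_length(rep$kept_gene_ids, 0L)
  expect_true(all(rep$dropped == "no_strong_edge"))
})

test_that("drug responses carry the planted cluster shifts and missingness", {
  cfg <- generator_config(n_genes = 50, n_decoy_genes = 0, n_samples = 400,
                          n_modules = 2, n_clusters = 4, n_drugs = 10,
                          missing_fraction_a = 0.25, missing_fraction_b = 0.45,
                          seed = 12)
  g <- generate_paired_expression(cfg)
  d <- generate_drug_responses(g$truth)
  expect_identical(d$drugs_a$metric, "ic50_uM")
  # realized missingness concentrates near the configured fractions
  expect_lt(abs(mean(is.na(d$drugs_a$values)) - 0.25), 0.02)
  expect_lt(abs(mean(is.na(d$drugs_b$values)) - 0.45), 0.02)
  # planted sensitive shift raises the common-scale sensitivity, resistant
  # lowers it
  sens <- transform_sensitivity(d$drugs_a)
  eff <- g$truth$drug_effects
  for (i in c(1, 2)) {  # one "sensitive", one "resistant" drug
    v <- sens[[i]]$values
    inc <- g$truth$clusters[names(v)] == eff$cluster[i]
    delta <- mean(v[inc], na.rm = TRUE) - mean(v[!inc], na.rm = TRUE)
    if (eff$sign[i] == "sensitive") expect_gt(delta, 1)
    else expect_lt(delta, -1)
  }
  # effects referencing unknown clusters are rejected
  bad <- g$truth
  bad$drug_effects$cluster[1] <- "cluster_99"
  expect_error(generate_drug_responses(bad), "unknown cluster")
})

test_that("mutation generation is seeded, binary, and enriched where planted", {
  cfg <- generator_config(n_genes = 50, n_decoy_genes = 0, n_samples = 300,
                          n_modules = 2, n_clusters = 4,
                          n_mutation_genes = 4, mutation_base_rate = 0.1,
                          mutation_odds = 8, seed = 13)
  g <- generate_paired_expression(cfg)
  m1 <- generate_mutations(g$truth)
  expect_identical(m1, generate_mutations(g$truth))
  expect_true(all(m1 %in% c(0, 1)))
  eff <- g$truth$mutation_effects
  inc <- g$truth$clusters[colnames(m1)] == eff$cluster[1]
  expect_gt(mean(m1[eff$gene_id[1], inc]), mean(m1[eff$gene_id[1], !inc]))
  # multipliers below 1 are rejected (enrichment only)
  bad <- g$truth
  bad$mutation_effects$odds_multiplier[1] <- 0.5
  expect_error(generate_mutations(bad), ">= 1")
})

test_that("a written bundle loads back through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 20)
  b <- write_synthetic_bundle(cfg, dir)
  expect_true(all(file.exists(b$paths)))
  expect_equal(read_expression_matrix(b$paths[["expr_a"]]), b$expr_a)
  expect_equal(read_drug_response(b$paths[["drugs_a"]],
                                  metric = "ic50_uM")$values,
               b$drugs_a$values)
  expect_equal(read_mutation_matrix(b$paths[["mutations"]]), b$mutations)
  gr <- read_interaction_graph(b$paths[["graph"]])
  expect_equal(nrow(gr), nrow(b$graph))
  truth <- jsonlite::read_json(b$paths[["truth"]])
  expect_named(truth$modules, names(b$truth$modules))
})
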