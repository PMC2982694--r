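# Synthetic-data generator: determinism, planted structure, round trips.

test_that("generate_network is deterministic, connected and validated", {
  n1 <- generate_network(60, "scale_free", 2, seed = 4)
  n2 <- generate_network(60, "scale_free", 2, seed = 4)
  expect_identical(n1$edges, n2$edges)
  expect_true(igraph::is_connected(as_igraph(n1)))

  er <- generate_network(5, "erdos_renyi", 1, seed = 1)
  expect_equal(nrow(er$edges), 10)   # complete graph on 5 nodes

  expect_error(generate_network(3, "scale_free", 2), "at least 5")
  expect_error(generate_network(10, "erdos_renyi", 0), "param")
})

test_that("planted modules are connected, contain targets, decay by hop", {
  net <- generate_network(100, "scale_free", 2, seed = 2)
  tg <- net$nodes[c(3, 7)]
  pl <- plant_perturbation(net, tg, module_size = 10, seed = 6)
  expect_length(pl$module, 10)
  expect_true(all(tg %in% pl$module))
  expect_true(connected_to_targets(pl$module,
                                   net$edges[net$edges$gene_a %in% pl$module &
                                             net$edges$gene_b %in% pl$module, ],
                                   tg))
  expect_equal(unname(pl$hops[tg]), c(0L, 0L))
  mu <- log2(pl$true_ratios[names(pl$hops)])
  expect_equal(unname(mu), unname(2 * 0.9 ^ pl$hops), tolerance = 1e-12)
  expect_error(plant_perturbation(net, tg, module_size = 500),
               "cannot reach")
})

test_that("identical seeds reproduce the emitted matrices byte for byte", {
  net <- generate_network(40, "scale_free", 2, seed = 3)
  a <- plant_perturbation(net, net$nodes[1], module_size = 5, seed = 9)
  b <- plant_perturbation(net, net$nodes[1], module_size = 5, seed = 9)
  expect_identical(a$probe_matrix, b$probe_matrix)
  expect_identical(a$meta, b$meta)
})

test_that("preprocessing recovers planted ratios from emitted files", {
  net <- generate_network(50, "scale_free", 2, seed = 8)
  # noise-free, no decay: every module gene comes back at ratio 4 exactly
  pl0 <- plant_perturbation(net, net$nodes[4], module_size = 8,
                            effect_size = 2, decay = 1, noise_sd = 0,
                            seed = 10, drug = "D0")
  prof0 <- dataset_profile(pl0)
  expect_equal(unname(prof0$ratios[pl0$module]), rep(4, 8),
               tolerance = 1e-12)
  off <- setdiff(names(prof0$ratios), pl0$module)
  expect_equal(unname(prof0$ratios[off]), rep(1, length(off)),
               tolerance = 1e-12)

  # noisy: every gene within 4 * noise_sd / sqrt(replicates) on log2 scale
  pl <- plant_perturbation(net, net$nodes[4], module_size = 8,
                           effect_size = 2, decay = 0.9, noise_sd = 0.2,
                           seed = 11, drug = "D1")
  prof <- dataset_profile(pl)
  n_reps <- 6   # 2 case replicates x 3 batches
  err <- abs(log2(prof$ratios[net$nodes]) - log2(pl$true_ratios[net$nodes]))
  expect_true(all(err < 4 * 0.2 / sqrt(n_reps)))

  # near-null perturbation keeps weights near zero
  plz <- plant_perturbation(net, net$nodes[4], module_size = 8,
                            effect_size = 0, noise_sd = 0.1, seed = 12)
  profz <- dataset_profile(plz)
  expect_true(all(profz$weights < 4 * 0.1))
})

test_that("combo truth follows the additive and synergistic rules", {
  sc <- make_scenario(seed = 13, n_nodes = 60, n_drugs = 2, noise_sd = 0)
  ra <- sc$drugs$DRUG1$true_ratios
  rb <- sc$drugs$DRUG2$true_ratios
  add <- make_combo_truth(sc, "DRUG1", "DRUG2", "additive")
  expect_equal(add$true_ratios, pmax(1 + (ra - 1) + (rb - 1), 0.01),
               tolerance = 1e-12)
  syn <- make_combo_truth(sc, "DRUG1", "DRUG2", "synergistic_on_disease",
                          boost = 2)
  dg <- intersect(names(ra), sc$disease_genes)
  expect_equal(syn$true_ratios[dg],
               pmax(1 + 2 * ((ra[dg] - 1) + (rb[dg] - 1)), 0.01),
               tolerance = 1e-12)
  other <- setdiff(names(ra), dg)
  expect_equal(syn$true_ratios[other], add$true_ratios[other],
               tolerance = 1e-12)
  expect_error(make_combo_truth(sc, "DRUG1", "DRUG2",
                                "synergistic_on_disease", boost = 1.2),
               "1.5")
})

test_that("scenario gene sets have the declared sizes and placement", {
  sc <- make_scenario(seed = 17)
  expect_length(sc$disease_genes, 20)
  expect_length(sc$essential_genes, 30)
  expect_length(intersect(sc$disease_genes, sc$essential_genes), 3)
  expect_length(sc$drugs, 5)
  for (d in sc$drugs) {
    expect_true(all(d$targets %in% sc$network$nodes))
    expect_true(all(d$targets %in% d$module))
  }
  # identical seed, identical scenario
  sc2 <- make_scenario(seed = 17)
  expect_identical(sc$disease_genes, sc2$disease_genes)
  expect_identical(sc$drugs$DRUG3$probe_matrix, sc2$drugs$DRUG3$probe_matrix)
})

test_that("written fixtures rebuild the scenario network exactly", {
  sc <- make_scenario(seed = 19, n_nodes = 60, n_drugs = 2)
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir)
  expect_true(all(file.exists(paths)))
  net <- build_background_network(
    ppi = read_interactions(paths["ppi"], "ppi"),
    pdi = read_interactions(paths["pdi"], "protein_dna"),
    signaling = read_interactions(paths["signaling"], "signaling"),
    expressed = read_gene_set(paths["expressed"]),
    min_methods = 2)
  expect_identical(net$nodes, sc$network$nodes)
  expect_identical(net$edges[, c("gene_a", "gene_b")],
                   sc$network$edges[, c("gene_a", "gene_b")])
  # every emitted table parses by the package's own readers
  expect_s3_class(read_metadata(paths["meta"]), "data.frame")
  expect_true(is.matrix(read_probe_matrix(paths["matrix"])))
  tmap <- read_targets(paths["targets"])
  expect_identical(sort(names(tmap)), c("DRUG1", "DRUG2"))
  expect_identical(tmap$DRUG1, sc$drugs$DRUG1$targets)
})
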