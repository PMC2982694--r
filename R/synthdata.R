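# Self-contained synthetic fixtures: networks, planted perturbation
# modules, probe-level case/control matrices with metadata, gene sets.
# The generator emulates the statistical structure the pipeline assumes
# (multiplicative expression noise, target-rooted propagation of drug
# effect) at a scale where the whole pipeline runs in seconds.

#' Generate a random background network
#'
#' Scale-free networks use preferential attachment (`param` = edges added
#' per new node); Erdos-Renyi networks use edge probability `param`.  The
#' largest connected component is retained and nodes are renamed to
#' `G0001, G0002, ...`.  Identical seeds give identical networks.
#'
#' @param n_nodes number of nodes before the component step (>= 5)
#' @param model `"scale_free"` or `"erdos_renyi"`
#' @param param attachment count (scale-free, >= 1) or edge probability
#'   (Erdos-Renyi, in (0, 1])
#' @param seed integer RNG seed
#' @return a connected `molecular_network`
#' @export
generate_network <- function(n_nodes, model = c("scale_free", "erdos_renyi"),
                             param = 2, seed = 1) {
  model <- match.arg(model)
  if (n_nodes < 5) stop("n_nodes must be at least 5")
  set.seed(seed)
  g <- switch(model,
    scale_free = {
      if (param < 1) stop("scale_free requires param >= 1")
      igraph::sample_pa(n_nodes, m = param, directed = FALSE)
    },
    erdos_renyi = {
      if (param <= 0 || param > 1)
        stop("erdos_renyi requires param in (0, 1]")
      igraph::sample_gnp(n_nodes, param)
    })
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))
  ed <- igraph::as_data_frame(g, what = "edges")
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  net <- molecular_network(
    data.frame(gene_a = ed$from, gene_b = ed$to, stringsAsFactors = FALSE),
    nodes = igraph::V(g)$name)
  suppressWarnings(largest_component(net))
}

# breadth-first module growth from the targets; random order inside a hop
# level (driven by the caller's RNG state).  Returns gene -> hop distance.
grow_module <- function(net, targets, module_size) {
  adj <- adjacency_list(net)
  targets <- intersect(norm_symbol(targets), net$nodes)
  if (length(targets) == 0) stop("no valid targets for module growth")
  if (module_size < length(targets))
    stop("module_size smaller than the number of targets")
  dist <- stats::setNames(rep(0L, length(targets)), targets)
  frontier <- targets
  d <- 0L
  while (length(dist) < module_size) {
    d <- d + 1L
    cand <- setdiff(unique(unlist(adj[frontier])), names(dist))
    if (length(cand) == 0)
      stop("module cannot reach the requested size from these targets")
    cand <- if (length(cand) > 1) sample(cand) else cand
    take <- utils::head(cand, module_size - length(dist))
    dist[take] <- d
    frontier <- cand
  }
  dist
}

# emit a probe-level case/control data set for one treatment whose true
# per-gene log2 ratio is `mu`.  Two probes per gene, one extra pseudo-symbol
# probe, >= 2 batches (ids "2" and "2a" exercise the batch merge), a decoy
# perturbagen so batches survive the single-drug filter, and one off-cell-
# line case/control pair that the cell-line filter must remove.
emit_dataset <- function(genes, mu, drug, dose, noise_sd,
                         batches = c("2", "2a", "3"),
                         n_case_reps = 2, n_controls = 2,
                         baseline = 100, cell_line = "MCF7") {
  stopifnot(identical(names(mu), genes))
  probes <- c(paste0("p_", rep(genes, each = 2), "_", 1:2), "p_pseudo")
  # two dedicated symbols carried only by the pseudo probe; keeps the
  # "A /// B" collapsing rule exercised without touching network genes
  probe_map <- data.frame(
    probe = probes,
    symbol = c(rep(genes, each = 2), "X9991 /// X9992"),
    stringsAsFactors = FALSE)
  probe_mu <- c(rep(mu, each = 2), 0)
  sample_value <- function(shift) {
    baseline * 2 ^ (shift + stats::rnorm(length(probes), 0, noise_sd))
  }
  cols <- list()
  meta <- list()
  add_sample <- function(id, batch, cl, pert, dse, ctl, shift) {
    cols[[id]] <<- sample_value(shift)
    meta[[id]] <<- data.frame(sample_id = id, batch_id = batch,
                              cell_line = cl, perturbagen = pert,
                              dose = dse, control_ids = ctl,
                              stringsAsFactors = FALSE)
  }
  for (b in batches) {
    ctl_ids <- sprintf("s_%s_b%s_ctl%02d", drug, b, seq_len(n_controls))
    for (id in ctl_ids)
      add_sample(id, b, cell_line, "CONTROL", 0, "", 0)
    ctl_field <- paste(ctl_ids, collapse = ";")
    for (r in seq_len(n_case_reps))
      add_sample(sprintf("s_%s_b%s_case%02d", drug, b, r), b, cell_line,
                 drug, dose, ctl_field, probe_mu)
    # decoy perturbagen keeps the batch multi-drug
    add_sample(sprintf("s_%s_b%s_decoy", drug, b), b, cell_line,
               "DECOY", dose, ctl_field, 0)
  }
  # off-cell-line pair, must be filtered out
  b1 <- batches[1]
  add_sample(sprintf("s_%s_b%s_xctl", drug, b1), b1, "HL60",
             "CONTROL", 0, "", 0)
  add_sample(sprintf("s_%s_b%s_xcase", drug, b1), b1, "HL60", drug, dose,
             sprintf("s_%s_b%s_xctl", drug, b1), probe_mu)
  mat <- do.call(cbind, cols)
  rownames(mat) <- probes
  list(probe_matrix = mat,
       probe_map = probe_map,
       meta = do.call(rbind, c(meta, make.row.names = FALSE)))
}

#' Plant a drug perturbation on a network
#'
#' Grows a connected module of `module_size` genes around the targets by
#' breadth-first expansion; a module gene at hop distance `d` from its
#' nearest target receives a true log2 expression ratio of
#' `effect_size * decay^d`, all other genes 0.  Probe-level case/control
#' samples are then emitted with independent Normal log2-scale noise of
#' standard deviation `noise_sd` per probe per sample (log-normal on the
#' intensity scale), controls at the fixed baseline intensity.
#'
#' @param net a `molecular_network`
#' @param targets target genes of the drug (in `net`)
#' @param module_size number of genes in the planted module
#' @param effect_size log2 ratio at the targets
#' @param decay per-hop attenuation in (0, 1]
#' @param noise_sd log2-scale noise standard deviation
#' @param seed integer RNG seed
#' @param drug treatment label (default `"DRUG"`)
#' @param dose nominal dose recorded in the metadata
#' @return list with `probe_matrix`, `probe_map`, `meta` (the emitted
#'   files' contents), `module` (character vector), `hops` (named hop
#'   distances), `true_ratios` (named, `2^mu`), `drug`, `dose`, `targets`
#' @export
plant_perturbation <- function(net, targets, module_size = 12,
                               effect_size = 2, decay = 0.9,
                               noise_sd = 0.2, seed = 1,
                               drug = "DRUG", dose = 10) {
  stopifnot(inherits(net, "molecular_network"))
  set.seed(seed)
  hops <- grow_module(net, targets, module_size)
  genes <- net$nodes
  mu <- stats::setNames(rep(0, length(genes)), genes)
  mu[names(hops)] <- effect_size * decay ^ hops
  ds <- emit_dataset(genes, mu, drug, dose, noise_sd)
  c(ds, list(module = sort(names(hops)), hops = hops,
             true_ratios = 2 ^ mu, drug = drug, dose = dose,
             targets = intersect(norm_symbol(targets), genes)))
}

#' Ground-truth data for a drug combination
#'
#' Combines the two member drugs' planted (noise-free) ratios under the
#' chosen interaction and emits a probe-level data set for the combined
#' treatment.  `"additive"` sums the deviations from 1;
#' `"synergistic_on_disease"` additionally multiplies the summed deviation
#' of every disease gene by `boost` (>= 1.5).  True ratios are floored at
#' 0.01.
#'
#' @param scenario a `synthetic_scenario` (see [make_scenario()])
#' @param drug_a,drug_b member drug labels in the scenario
#' @param interaction `"additive"` or `"synergistic_on_disease"`
#' @param boost disease-gene deviation multiplier (synergistic mode)
#' @param seed RNG seed for the emitted noise
#' @return as [plant_perturbation()], with `true_ratios` the combined truth
#' @export
make_combo_truth <- function(scenario, drug_a, drug_b,
                             interaction = c("additive",
                                             "synergistic_on_disease"),
                             boost = 2, seed = 1) {
  interaction <- match.arg(interaction)
  stopifnot(inherits(scenario, "synthetic_scenario"),
            all(c(drug_a, drug_b) %in% names(scenario$drugs)))
  if (interaction == "synergistic_on_disease" && boost < 1.5)
    stop("synergistic boost must be at least 1.5")
  ra <- scenario$drugs[[drug_a]]$true_ratios
  rb <- scenario$drugs[[drug_b]]$true_ratios
  stopifnot(identical(names(ra), names(rb)))
  dev <- (ra - 1) + (rb - 1)
  if (interaction == "synergistic_on_disease") {
    dg <- intersect(names(dev), scenario$disease_genes)
    dev[dg] <- dev[dg] * boost
  }
  truth <- pmax(1 + dev, 0.01)
  set.seed(seed)
  label <- paste(drug_a, drug_b, sep = "&")
  ds <- emit_dataset(names(truth), log2(truth), label, 10,
                     scenario$noise_sd)
  c(ds, list(true_ratios = truth, drug = label,
             dose = 10,
             targets = sort(unique(c(scenario$drugs[[drug_a]]$targets,
                                     scenario$drugs[[drug_b]]$targets)))))
}

#' Build a complete synthetic screening scenario
#'
#' One call produces everything the pipeline consumes: a connected
#' scale-free background network, a panel of drugs with planted affected
#' modules and probe-level case/control data, and disease / essential gene
#' sets.  Disease genes are drawn partly from the planted modules
#' (`disease_frac_in_modules`) so drug efficacy is detectable; essential
#' genes are drawn outside the modules (toxicity-neutral drugs), with a
#' small overlap with the disease set to exercise the "innocent essential
#' gene" exclusion.  Identical seeds give identical scenarios.
#'
#' @param seed integer RNG seed
#' @param n_nodes network size before the component step (default 200)
#' @param n_drugs number of drugs (default 5)
#' @param targets_per_drug 1 or 2 targets each (default alternates)
#' @param module_size planted module size (default 8: two member modules
#'   fit together inside the flow model's 10% subnetwork-size cap)
#' @param effect_size log2 ratio at the targets (default 2)
#' @param decay per-hop attenuation (default 0.9)
#' @param noise_sd log2-scale probe noise (default 0.2)
#' @param n_disease,n_essential gene-set sizes (defaults 20 and 30)
#' @param n_overlap essential genes that are also disease genes (default 3)
#' @param disease_frac_in_modules fraction of disease genes sampled from
#'   the planted modules (default 0.5; 0 makes every module disjoint from
#'   the disease set)
#' @return object of class `synthetic_scenario`: `network`,
#'   `disease_genes`, `essential_genes`, `drugs` (named list with
#'   `targets`, `module`, `true_ratios` and the emitted data), `noise_sd`,
#'   `seed`
#' @export
make_scenario <- function(seed = 1, n_nodes = 200, n_drugs = 5,
                          targets_per_drug = NULL, module_size = 8,
                          effect_size = 2, decay = 0.9, noise_sd = 0.2,
                          n_disease = 20, n_essential = 30, n_overlap = 3,
                          disease_frac_in_modules = 0.5) {
  net <- generate_network(n_nodes, "scale_free", 2, seed = seed)
  set.seed(seed + 1)
  nodes <- net$nodes
  deg <- table(c(net$edges$gene_a, net$edges$gene_b))
  hubs <- names(deg)[deg >= 2]
  if (is.null(targets_per_drug))
    targets_per_drug <- rep_len(c(1, 2), n_drugs)
  target_pool <- sample(hubs)
  drugs <- list()
  used <- character(0)
  for (k in seq_len(n_drugs)) {
    tg <- utils::head(setdiff(target_pool, used), targets_per_drug[k])
    used <- c(used, tg)
    drugs[[sprintf("DRUG%d", k)]] <- list(targets = sort(tg))
  }
  for (k in seq_len(n_drugs)) {
    d <- sprintf("DRUG%d", k)
    pl <- plant_perturbation(net, drugs[[d]]$targets,
                             module_size = module_size,
                             effect_size = effect_size, decay = decay,
                             noise_sd = noise_sd, seed = seed + 1 + k,
                             drug = d)
    drugs[[d]] <- pl
  }
  set.seed(seed + 2)
  module_union <- sort(unique(unlist(lapply(drugs, `[[`, "module"))))
  off_module <- setdiff(nodes, module_union)
  n_in <- round(n_disease * disease_frac_in_modules)
  n_in <- min(n_in, length(module_union))
  # spread in-module disease genes evenly over the drugs' exclusive module
  # parts, so every drug has detectable efficacy
  share <- ceiling(n_in / n_drugs)
  disease <- character(0)
  for (d in names(drugs)) {
    part <- setdiff(drugs[[d]]$module,
                    c(disease, unlist(lapply(drugs[names(drugs) != d],
                                             `[[`, "module"))))
    disease <- c(disease,
                 sample(part, min(share, length(part), n_in - length(disease))))
  }
  if (length(disease) < n_in)
    disease <- c(disease, sample(setdiff(module_union, disease),
                                 n_in - length(disease)))
  disease <- c(disease, sample(off_module, n_disease - length(disease)))
  ess_pool <- setdiff(off_module, disease)
  essential <- sample(ess_pool, n_essential - n_overlap)
  overlap_pool <- setdiff(disease, module_union)
  if (length(overlap_pool) < n_overlap) overlap_pool <- disease
  essential <- c(essential, sample(overlap_pool, n_overlap))
  structure(list(network = net,
                 disease_genes = sort(disease),
                 essential_genes = sort(essential),
                 drugs = drugs,
                 noise_sd = noise_sd,
                 module_size = module_size,
                 seed = seed),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic_scenario (seed %d): %d-gene network, %d drugs, %d disease / %d essential genes\n",
    x$seed, length(x$network$nodes), length(x$drugs),
    length(x$disease_genes), length(x$essential_genes)))
  invisible(x)
}

#' Gene-level expression profiles for every scenario drug
#'
#' Runs the preprocessing pipeline (probe collapsing, sample filtering,
#' case/control aggregation, ratios, weights) on each drug's emitted data.
#'
#' @param scenario a `synthetic_scenario`
#' @param weight_fn see [compute_weights()]
#' @return named list of `expr_profile` objects
#' @export
scenario_profiles <- function(scenario, weight_fn = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  out <- lapply(names(scenario$drugs), function(d) {
    dataset_profile(scenario$drugs[[d]], weight_fn)
  })
  stats::setNames(out, names(scenario$drugs))
}

#' Profile from one emitted data set
#'
#' @param dataset result of [plant_perturbation()] or [make_combo_truth()]
#' @param weight_fn see [compute_weights()]
#' @return an `expr_profile`
#' @export
dataset_profile <- function(dataset, weight_fn = NULL) {
  gm <- suppressMessages(
    collapse_probes(dataset$probe_matrix, dataset$probe_map))
  meta <- filter_samples(dataset$meta)
  suppressMessages(
    drug_profile(gm, meta, dataset$drug, dose = dataset$dose,
                 weight_fn = weight_fn))
}
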