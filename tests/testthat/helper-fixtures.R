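# Shared fixture builders: everything is generated in code at test time.

path_net <- function(genes) {
  molecular_network(data.frame(gene_a = genes[-length(genes)],
                               gene_b = genes[-1]))
}

star_net <- function(center, leaves) {
  molecular_network(data.frame(gene_a = center, gene_b = leaves))
}

# random connected weighted instance for the flow-model oracle suite:
# |V| <= 12, 1-3 targets, feasible R
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(5:12, 1)
  genes <- sprintf("N%02d", seq_len(n))
  # random spanning tree plus extra edges
  ed <- data.frame(gene_a = genes[1], gene_b = genes[2])
  for (k in 3:n) {
    ed <- rbind(ed, data.frame(gene_a = sample(genes[seq_len(k - 1)], 1),
                               gene_b = genes[k]))
  }
  extra <- sample(n, 1)
  for (k in seq_len(extra)) {
    pair <- sample(genes, 2)
    ed <- rbind(ed, data.frame(gene_a = pair[1], gene_b = pair[2]))
  }
  key <- paste(pmin(ed$gene_a, ed$gene_b), pmax(ed$gene_a, ed$gene_b))
  ed <- ed[!duplicated(key), ]
  net <- molecular_network(ed)
  w <- stats::setNames(round(stats::runif(n, 0, 5), 3), genes)
  w[sample(n, max(1, floor(n / 3)))] <- 0
  targets <- sample(genes, sample(1:3, 1))
  rb <- r_bounds(net, targets)
  rng <- rb$R_min:min(n, rb$R_min + 4)
  R <- rng[sample.int(length(rng), 1)]
  list(net = net, weights = w, targets = sort(targets), R = R, seed = seed)
}

# Jaccard index between two gene sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# every gene of `genes` reachable from a target through `genes` only
# (independent connectivity check via igraph)
connected_to_targets <- function(genes, edges, targets) {
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE, vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership
  all(comp %in% comp[targets])
}
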