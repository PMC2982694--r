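# Readers and writers for the tab-separated formats shared by the pipeline.

#' Read an interaction edge list
#'
#' Tab-separated file with header `gene_a<TAB>gene_b[<TAB>evidence_count]`;
#' the evidence column is optional for protein-DNA and signaling lists.
#'
#' @param path file path
#' @param source_type one of `"ppi"`, `"protein_dna"`, `"signaling"`
#' @return interaction record data.frame (see [interaction_records()])
#' @export
read_interactions <- function(path, source_type = "ppi") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  interaction_records(df, source_type)
}

#' Write a network as an edge list (plus node sidecar)
#'
#' Writes `gene_a<TAB>gene_b<TAB>sources` and a `<path>.nodes` file with
#' one gene per line (isolated nodes included).
#'
#' @param net a `molecular_network`
#' @param path output TSV path
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(net$nodes, paste0(path, ".nodes"))
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path edge-list TSV path (a `<path>.nodes` sidecar is used when
#'   present, so isolated nodes round-trip)
#' @return a `molecular_network`
#' @export
read_network <- function(path) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE)
  nodes <- if (file.exists(paste0(path, ".nodes")))
    readLines(paste0(path, ".nodes")) else NULL
  molecular_network(ed, nodes = nodes)
}

#' Export a network or subnetwork to GraphML
#'
#' @param x a `molecular_network` or `subnetwork_result`
#' @param path output path
#' @export
write_graphml <- function(x, path) {
  g <- if (inherits(x, "molecular_network")) {
    as_igraph(x)
  } else {
    igraph::graph_from_data_frame(
      x$edges, directed = FALSE, vertices = data.frame(name = x$genes))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a subnetwork in SIF format
#'
#' One `gene_a<TAB>interacts<TAB>gene_b` line per induced edge; isolated
#' genes get a bare line.
#'
#' @param subnet a `subnetwork_result`
#' @param path output path
#' @export
write_sif <- function(subnet, path) {
  lines <- sprintf("%s\tinteracts\t%s", subnet$edges$gene_a,
                   subnet$edges$gene_b)
  iso <- setdiff(subnet$genes,
                 unique(c(subnet$edges$gene_a, subnet$edges$gene_b)))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Write a subnetwork result as JSON
#' @param subnet a `subnetwork_result`
#' @param path output path
#' @export
write_subnetwork_json <- function(subnet, path) {
  jsonlite::write_json(
    list(genes = subnet$genes,
         edges = subnet$edges,
         targets = subnet$targets,
         R_requested = subnet$R_requested,
         objective = subnet$objective,
         normalized_score = subnet$normalized_score,
         lp_integral = subnet$lp_integral),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a gene set
#'
#' Plain one-symbol-per-line files or GMT (name, description, then genes,
#' tab-separated; all sets in the file are pooled).
#'
#' @param path file path; `.gmt` extension switches to GMT parsing
#' @return character vector of gene symbols
#' @export
read_gene_set <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    rows <- strsplit(readLines(path), "\t", fixed = TRUE)
    genes <- unlist(lapply(rows, function(r) r[-(1:2)]))
  } else {
    genes <- readLines(path)
  }
  sort(unique(norm_symbol(genes[nzchar(trimws(genes))])))
}

#' Read a probe-level expression matrix
#'
#' Tab-separated, first column = probe id, header = sample ids.
#'
#' @param path file path
#' @return numeric matrix, probes x samples
#' @export
read_probe_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a probe-level matrix
#' @param mat probes x samples matrix
#' @param path output path
#' @export
write_probe_matrix <- function(mat, path) {
  df <- data.frame(probe = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the probe-to-symbol map (`probe<TAB>symbol`)
#' @param path file path
#' @return data.frame with columns `probe`, `symbol`
#' @export
read_probe_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write a sample metadata table
#' @param path file path
#' @return metadata data.frame (see [filter_samples()])
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = c(control_ids = "character"))
  df$control_ids[is.na(df$control_ids)] <- ""
  df
}

#' Read / write an expression profile (`gene<TAB>ratio<TAB>weight`)
#' @param path file path
#' @param label treatment label (defaults to the file stem)
#' @return an `expr_profile`
#' @export
read_profile <- function(path, label = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  expression_profile(label, stats::setNames(df$ratio, df$gene))
}

#' @rdname read_profile
#' @param profile an `expr_profile`
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(gene = names(profile$ratios),
                   ratio = unname(profile$ratios),
                   weight = unname(profile$weights),
                   stringsAsFactors = FALSE)
  if (!is.null(profile$mode_used))
    df$mode_used <- unname(profile$mode_used)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-to-target table (`drug<TAB>targets`, semicolon-separated)
#' @param path file path
#' @return named list: drug -> character vector of targets
#' @export
read_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(lapply(df$targets, split_ids), df$drug)
}

#' Write scenario fixtures to disk
#'
#' Emits every file the pipeline consumes: raw interaction edge lists with
#' planted cleaning decoys (self-loops, duplicate pairs, under-supported
#' interactions, unexpressed genes and a detached expressed component, so
#' the network-assembly filters all fire), the expressed-gene list, the
#' combined probe matrix / probe map / metadata over all drugs, gene sets
#' and the drug-target table.  [build_background_network()] on the emitted
#' edge lists reproduces `scenario$network` exactly.
#'
#' @param scenario a `synthetic_scenario`
#' @param dir output directory (created if needed)
#' @return named character vector of file paths
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(scenario$seed + 97)
  net <- scenario$network
  ed <- net$edges
  n <- nrow(ed)
  src <- sample(c("ppi", "pdi", "signaling"), n, replace = TRUE,
                prob = c(0.7, 0.15, 0.15))
  ppi <- ed[src == "ppi", , drop = FALSE]
  ppi$evidence_count <- sample(2:4, nrow(ppi), replace = TRUE)
  # decoys: self-loop, duplicate with weaker evidence, under-supported
  # duplicate of a pdi edge, edges among unexpressed genes, and a small
  # detached expressed component
  pdi <- ed[src == "pdi", , drop = FALSE]
  sig <- ed[src == "signaling", , drop = FALSE]
  decoys <- data.frame(
    gene_a = c(net$nodes[1], ppi$gene_a[1], pdi$gene_a[1],
               "U0001", "U0002"),
    gene_b = c(net$nodes[1], ppi$gene_b[1], pdi$gene_b[1],
               "U0002", "U0003"),
    evidence_count = c(5, 1, 1, 3, 3))
  ppi_out <- rbind(ppi[, c("gene_a", "gene_b", "evidence_count")], decoys)
  sig_out <- rbind(sig[, c("gene_a", "gene_b")],
                   data.frame(gene_a = "Z0001", gene_b = "Z0002"))
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             pdi = file.path(dir, "pdi.tsv"),
             signaling = file.path(dir, "signaling.tsv"),
             expressed = file.path(dir, "expressed.txt"),
             matrix = file.path(dir, "matrix.tsv"),
             probe_map = file.path(dir, "probe_map.tsv"),
             meta = file.path(dir, "meta.tsv"),
             disease = file.path(dir, "disease_genes.txt"),
             essential = file.path(dir, "essential_genes.txt"),
             targets = file.path(dir, "targets.tsv"))
  utils::write.table(ppi_out, paths["ppi"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pdi[, c("gene_a", "gene_b")], paths["pdi"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sig_out, paths["signaling"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(net$nodes, "Z0001", "Z0002"), paths["expressed"])
  mats <- lapply(scenario$drugs, `[[`, "probe_matrix")
  mat <- do.call(cbind, mats)
  write_probe_matrix(mat, paths["matrix"])
  utils::write.table(scenario$drugs[[1]]$probe_map, paths["probe_map"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- do.call(rbind, c(lapply(scenario$drugs, `[[`, "meta"),
                           make.row.names = FALSE))
  utils::write.table(meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(scenario$disease_genes, paths["disease"])
  writeLines(scenario$essential_genes, paths["essential"])
  tg <- data.frame(
    drug = names(scenario$drugs),
    targets = vapply(scenario$drugs,
                     function(d) paste(d$targets, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(tg, paths["targets"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
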