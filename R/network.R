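# Background molecular interaction network: assembly and filtering.

#' Construct a molecular interaction network
#'
#' A `molecular_network` is an undirected simple graph over gene symbols with
#' optional non-negative node weights (differential-expression magnitudes).
#' Edges are stored as unordered pairs in canonical order (`gene_a < gene_b`);
#' self-loops and duplicate pairs are rejected.  Protein-DNA and signaling
#' edges are directional in their source databases, but the network keeps
#' every interaction undirected: the downstream flow model routes flow both
#' ways along each interaction, so only undirected reachability matters.
#'
#' @param edges data.frame with character columns `gene_a`, `gene_b` and an
#'   optional `sources` column (comma-separated provenance tags).
#' @param nodes optional character vector of node symbols; the union of edge
#'   endpoints is always included, extra entries become isolated nodes.
#' @param weights optional named numeric vector of non-negative node weights;
#'   names must be a subset of the node set.
#' @return object of class `molecular_network` with elements `nodes` (sorted
#'   character), `edges` (data.frame), `weights` (named numeric or NULL).
#' @export
molecular_network <- function(edges = NULL, nodes = NULL, weights = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        sources = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b") %in% names(edges)))
  a <- norm_symbol(edges$gene_a)
  b <- norm_symbol(edges$gene_b)
  if (any(a == b)) stop("self-loops are not allowed in a molecular_network")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  sources <- if ("sources" %in% names(edges)) as.character(edges$sources)
             else rep(NA_character_, length(lo))
  ed <- data.frame(gene_a = lo, gene_b = hi, sources = sources,
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL
  nd <- sort(unique(c(lo, hi, if (!is.null(nodes)) norm_symbol(nodes))))
  if (!is.null(weights)) {
    stopifnot(is.numeric(weights), !is.null(names(weights)))
    if (!all(names(weights) %in% nd))
      stop("weighted genes must belong to the node set")
    if (any(weights < 0)) stop("node weights must be non-negative")
  }
  structure(list(nodes = nd, edges = ed, weights = weights),
            class = "molecular_network")
}

# canonical gene-symbol form: trimmed, upper-cased
norm_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x)) || anyNA(x)) stop("empty or missing gene symbol")
  x
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("molecular_network: %d genes, %d interactions%s\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' Number of nodes / edges
#' @param net a `molecular_network`
#' @return character vector of gene symbols (`network_nodes`) or the edge
#'   data.frame (`network_edges`).
#' @export
network_nodes <- function(net) net$nodes

#' @rdname network_nodes
#' @export
network_edges <- function(net) net$edges

#' Convert to an igraph object
#'
#' Isolated nodes are preserved; the result is undirected and simple.
#'
#' @param net a `molecular_network`
#' @return an [igraph::graph] object
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "molecular_network"))
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Attach node weights to a network
#'
#' @param net a `molecular_network`
#' @param weights named numeric vector, names in `network_nodes(net)`;
#'   genes absent from `weights` implicitly weigh 0.
#' @return the network with `weights` set
#' @export
set_node_weights <- function(net, weights) {
  molecular_network(net$edges, nodes = net$nodes, weights = weights)
}

#' Normalise raw interaction records
#'
#' Trims and upper-cases symbols and fills defaults so that downstream
#' cleaning operates on a uniform table.
#'
#' @param records data.frame with columns `gene_a`, `gene_b` and optionally
#'   `evidence_count` (number of distinct experimental methods supporting a
#'   physical interaction; meaningful for PPI only, defaults to 0).
#' @param source_type one of `"ppi"`, `"protein_dna"`, `"signaling"`.
#' @return data.frame of interaction records with columns `gene_a`, `gene_b`,
#'   `source_type`, `evidence_count`, `directed`.
#' @export
interaction_records <- function(records,
                                source_type = c("ppi", "protein_dna",
                                                "signaling")) {
  source_type <- match.arg(source_type)
  stopifnot(is.data.frame(records),
            all(c("gene_a", "gene_b") %in% names(records)))
  ev <- if ("evidence_count" %in% names(records)) {
    as.integer(records$evidence_count)
  } else {
    rep(0L, nrow(records))
  }
  ev[is.na(ev)] <- 0L
  if (any(ev < 0)) stop("evidence_count must be non-negative")
  out <- data.frame(
    gene_a = if (nrow(records)) norm_symbol(records$gene_a) else character(),
    gene_b = if (nrow(records)) norm_symbol(records$gene_b) else character(),
    source_type = rep(source_type, nrow(records)),
    evidence_count = ev,
    directed = rep(source_type != "ppi", nrow(records)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Clean protein-protein interaction records
#'
#' Removes self-interactions, collapses duplicate unordered pairs (keeping
#' the best evidence count) and discards interactions supported by fewer
#' than `min_methods` distinct experimental methods.
#'
#' @param records interaction records with `source_type == "ppi"`
#'   (see [interaction_records()]).
#' @param min_methods minimum number of distinct experimental methods
#'   (default 2).
#' @return filtered record data.frame
#' @export
clean_ppi <- function(records, min_methods = 2) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(interaction_records(records, "ppi"))
  if (!all(records$source_type == "ppi"))
    stop("clean_ppi expects ppi records only")
  rec <- records[records$gene_a != records$gene_b, , drop = FALSE]
  if (nrow(rec)) {
    lo <- pmin(rec$gene_a, rec$gene_b)
    hi <- pmax(rec$gene_a, rec$gene_b)
    key <- paste(lo, hi, sep = "\r")
    best <- tapply(rec$evidence_count, key, max)
    keep <- !duplicated(key)
    rec <- rec[keep, , drop = FALSE]
    rec$gene_a <- lo[keep]
    rec$gene_b <- hi[keep]
    rec$evidence_count <- as.integer(best[paste(rec$gene_a, rec$gene_b,
                                                sep = "\r")])
    rec <- rec[rec$evidence_count >= min_methods, , drop = FALSE]
  }
  rec <- rec[order(rec$gene_a, rec$gene_b), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Integrate interaction sources into one network
#'
#' Takes the union of PPI, protein-DNA and signaling edges as unordered
#' pairs, dropping self-loops and collapsing duplicates across sources
#' (source tags are concatenated for provenance).
#'
#' @param ppi cleaned PPI records ([clean_ppi()])
#' @param pdi protein-DNA records (may be NULL)
#' @param signaling signaling-pathway records (may be NULL)
#' @return a `molecular_network`
#' @export
integrate_interactions <- function(ppi, pdi = NULL, signaling = NULL) {
  all_rec <- do.call(rbind, Filter(Negate(is.null), list(ppi, pdi, signaling)))
  if (is.null(all_rec) || nrow(all_rec) == 0) return(molecular_network())
  all_rec <- all_rec[all_rec$gene_a != all_rec$gene_b, , drop = FALSE]
  if (nrow(all_rec) == 0) return(molecular_network())
  lo <- pmin(all_rec$gene_a, all_rec$gene_b)
  hi <- pmax(all_rec$gene_a, all_rec$gene_b)
  key <- paste(lo, hi, sep = "\r")
  src <- vapply(split(all_rec$source_type, key),
                function(s) paste(sort(unique(s)), collapse = ","), "")
  keep <- !duplicated(key)
  molecular_network(data.frame(gene_a = lo[keep], gene_b = hi[keep],
                               sources = unname(src[key[keep]]),
                               stringsAsFactors = FALSE))
}

#' Restrict a network to expressed genes
#'
#' Keeps the induced subgraph over `expressed`; isolated nodes are retained
#' (the component step removes them later).
#'
#' @param net a `molecular_network`
#' @param expressed character vector of expressed gene symbols
#' @return a `molecular_network`
#' @export
restrict_to_expressed <- function(net, expressed) {
  stopifnot(inherits(net, "molecular_network"))
  if (length(net$nodes) == 0) return(net)
  expressed <- norm_symbol(expressed)
  keep_nodes <- intersect(net$nodes, expressed)
  ed <- net$edges
  ed <- ed[ed$gene_a %in% keep_nodes & ed$gene_b %in% keep_nodes, ,
           drop = FALSE]
  molecular_network(ed, nodes = keep_nodes)
}

#' Largest (weakly) connected component
#'
#' All edges are treated as undirected.  Ties on component size are broken
#' in favour of the component containing the lexicographically smallest
#' gene symbol.  An empty network is returned unchanged with a warning.
#'
#' @param net a `molecular_network`
#' @return a `molecular_network` restricted to the winning component
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "molecular_network"))
  if (length(net$nodes) == 0) {
    warning("largest_component: empty network")
    return(net)
  }
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest member symbol decides
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, "")
    best <- best[order(firsts)][1]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  ed <- net$edges
  ed <- ed[ed$gene_a %in% keep, , drop = FALSE]
  molecular_network(ed, nodes = keep)
}

#' Build the background molecular interaction network
#'
#' Full assembly pipeline: clean the PPI set, integrate the three sources,
#' restrict to genes observed in the expression data, and keep the largest
#' weakly connected component.
#'
#' @param ppi,pdi,signaling interaction record data.frames
#'   (see [interaction_records()]); `pdi`/`signaling` may be NULL
#' @param expressed character vector of expressed genes (NULL keeps all)
#' @param min_methods evidence threshold passed to [clean_ppi()]
#' @return a `molecular_network`
#' @export
build_background_network <- function(ppi, pdi = NULL, signaling = NULL,
                                     expressed = NULL, min_methods = 2) {
  net <- integrate_interactions(clean_ppi(ppi, min_methods), pdi, signaling)
  if (!is.null(expressed)) net <- restrict_to_expressed(net, expressed)
  largest_component(net)
}
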