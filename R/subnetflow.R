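# Drug-affected subnetwork extraction: dummy-rooted network-flow program
# solved through the GLPK stand-alone solver (glpsol), with LP relaxation
# for production use and exact binary mode for desk-scale verification.

#' Build the network-flow selection model
#'
#' Encodes the constrained maximum-weight connected subgraph problem rooted
#' at a dummy drug node `S`.  Each background interaction contributes two
#' opposite arcs; `S` has one outgoing arc to every drug target and no
#' incoming arcs.  The model:
#' \itemize{
#'   \item `sum_k Z[S, H_k] = R` — `R` units of flow enter via the targets;
#'   \item `inflow(i) - outflow(i) = x_i` for every gene `i` — a selected
#'     gene absorbs exactly one unit, so flow conservation forces
#'     `sum_i x_i = R` at any feasible point;
#'   \item `Z_ij <= R x_i` and `Z_ij <= R x_j` for every background arc —
#'     flow may only traverse selected genes, which makes every selected
#'     gene reachable from `S` through selected genes;
#'   \item `x_{H_k} = 1` — all targets are selected;
#'   \item `Z >= 0`, `x` in `[0,1]` (binary in exact mode);
#'   \item objective: maximize `sum_i w_i x_i`.
#' }
#'
#' @param net a `molecular_network`
#' @param weights named non-negative numeric vector (genes absent from it
#'   weigh 0); NULL uses the network's own weights
#' @param targets character vector of drug-target genes, all of which must
#'   be present in the network
#' @param R integer subnetwork size, `R >= length(targets)`
#' @return object of class `flow_model`
#' @export
build_flow_model <- function(net, weights = NULL, targets, R) {
  stopifnot(inherits(net, "molecular_network"))
  targets <- unique(norm_symbol(targets))
  missing <- setdiff(targets, net$nodes)
  if (length(missing))
    stop("target(s) not in the background network: ",
         paste(missing, collapse = ", "))
  R <- as.integer(R)
  if (R < length(targets))
    stop(sprintf("R = %d is smaller than the number of targets (%d)",
                 R, length(targets)))
  if (R > length(net$nodes)) stop("R exceeds the number of network nodes")
  if (is.null(weights)) weights <- net$weights
  w <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  if (!is.null(weights)) {
    weights <- weights[names(weights) %in% net$nodes]
    w[names(weights)] <- as.numeric(weights)
  }
  if (any(w < 0)) stop("node weights must be non-negative")
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  arcs <- rbind(cbind(idx[net$edges$gene_a], idx[net$edges$gene_b]),
                cbind(idx[net$edges$gene_b], idx[net$edges$gene_a]))
  structure(list(nodes = net$nodes, weights = w, arcs = arcs,
                 targets = targets, target_idx = unname(idx[targets]),
                 R = R),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf(
    "flow_model: %d genes, %d arcs (+%d dummy), %d target(s), R = %d\n",
    length(x$nodes), nrow(x$arcs), length(x$targets), length(x$targets),
    x$R))
  invisible(x)
}

# CPLEX-LP-format lines for a flow model
flow_model_lp <- function(model, exact) {
  w <- model$weights
  nz <- which(w > 0)
  obj <- if (length(nz)) {
    paste(sprintf("%.12g x%d", w[nz], nz), collapse = " + ")
  } else "0 x1"
  arcs <- model$arcs
  zname <- sprintf("z%d_%d", arcs[, 1], arcs[, 2])
  # per-node inflow/outflow terms
  n <- length(model$nodes)
  in_terms <- split(zname, factor(arcs[, 2], levels = seq_len(n)))
  out_terms <- split(zname, factor(arcs[, 1], levels = seq_len(n)))
  dummy <- sprintf("zS_%d", model$target_idx)
  for (k in seq_along(model$target_idx)) {
    ti <- model$target_idx[k]
    in_terms[[ti]] <- c(dummy[k], in_terms[[ti]])
  }
  cons <- character(0)
  cons <- c(cons, sprintf(" root: %s = %d",
                          paste(dummy, collapse = " + "), model$R))
  flow <- vapply(seq_len(n), function(i) {
    lhs <- paste(in_terms[[i]], collapse = " + ")
    if (length(out_terms[[i]]))
      lhs <- paste0(lhs, paste0(" - ", out_terms[[i]], collapse = ""))
    sprintf(" f%d: %s - x%d = 0", i, lhs, i)
  }, "")
  cap <- c(sprintf(" ca%d: %s - %d x%d <= 0",
                   seq_len(nrow(arcs)), zname, model$R, arcs[, 1]),
           sprintf(" cb%d: %s - %d x%d <= 0",
                   seq_len(nrow(arcs)), zname, model$R, arcs[, 2]))
  fix <- sprintf(" t%d: x%d = 1", seq_along(model$target_idx),
                 model$target_idx)
  bounds <- sprintf(" 0 <= x%d <= 1", seq_len(n))
  c("Maximize", paste0(" obj: ", obj), "Subject To",
    cons, flow, cap, fix,
    "Bounds", bounds,
    if (exact) c("Binary", sprintf(" x%d", seq_len(n))),
    "End")
}

# run glpsol on LP lines and return named activities + status
run_glpsol <- function(lp_lines, var_names) {
  glpsol <- Sys.which("glpsol")
  if (!nzchar(glpsol))
    stop("glpsol (GLPK) not found on the PATH")
  dir <- tempfile("flowlp")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  lp <- file.path(dir, "model.lp")
  out <- file.path(dir, "model.sol")
  writeLines(lp_lines, lp)
  log <- suppressWarnings(
    system2(glpsol, c("--lp", shQuote(lp), "-o", shQuote(out)),
            stdout = TRUE, stderr = TRUE))
  if (!file.exists(out))
    stop("glpsol failed: ", paste(utils::tail(log, 3), collapse = " | "))
  sol <- readLines(out)
  status <- sub("^Status:\\s*", "", grep("^Status:", sol, value = TRUE)[1])
  if (!grepl("OPTIMAL", status))
    return(list(status = status, values = NULL))
  col_at <- grep("^\\s*No\\. Column name", sol)
  body <- sol[(col_at + 2):length(sol)]
  stop_at <- which(!grepl("^\\s*\\d+ ", body))[1]
  if (!is.na(stop_at)) body <- body[seq_len(stop_at - 1)]
  # "   No. Column name  St   Activity ..." — name then an optional status
  # token ("B", "NU", "*", ...) then the activity number
  pref <- paste(unique(substring(var_names, 1, 1)), collapse = "")
  body <- body[grepl(sprintf("^\\s*\\d+\\s+[%s]", pref), body)]
  toks <- strsplit(trimws(body), "\\s+")
  nms <- vapply(toks, `[`, "", 2)
  t3 <- vapply(toks, `[`, "", 3)
  t4 <- vapply(toks, function(tk) if (length(tk) >= 4) tk[4] else NA, "")
  raw <- ifelse(grepl("^[-0-9.]", t3), t3, t4)
  vals <- as.numeric(raw)
  values <- stats::setNames(rep(0, length(var_names)), var_names)
  keep <- nms %in% var_names & !is.na(vals)
  values[nms[keep]] <- vals[keep]
  list(status = status, values = values)
}

#' Solve a flow model
#'
#' In relaxed mode (default) the binary selection variables are relaxed to
#' `[0,1]` and the linear program is solved; in exact mode the original
#' integer program is solved by branch-and-bound (practical only at desk
#' scale, used as a verification oracle).  The relaxed optimum is always an
#' upper bound on the exact optimum.
#'
#' @param model a `flow_model`
#' @param exact logical; solve the binary program instead of the relaxation
#' @return list with `x` (named selection values per gene), `objective`
#'   (`sum w_i x_i` recomputed from the solution), `status`, and `integral`
#'   (TRUE when every `x` is within 1e-6 of 0 or 1)
#' @export
solve_flow <- function(model, exact = FALSE) {
  stopifnot(inherits(model, "flow_model"))
  n <- length(model$nodes)
  xnames <- sprintf("x%d", seq_len(n))
  res <- run_glpsol(flow_model_lp(model, exact), xnames)
  if (is.null(res$values))
    stop(sprintf(
      "flow model infeasible (status: %s); check that target(s) %s can reach R = %d selected genes",
      res$status, paste(model$targets, collapse = ", "), model$R))
  x <- res$values[xnames]
  if (exact) x <- round(x)
  x <- pmin(pmax(x, 0), 1)
  names(x) <- model$nodes
  list(x = x,
       objective = sum(model$weights * x),
       status = res$status,
       integral = all(abs(x - round(x)) <= 1e-6))
}

#' Extract the affected subnetwork from a solution
#'
#' Genes with selection value above `threshold` form the subnetwork (an LP
#' solution may be fractional, so the extracted size can differ from `R`).
#' Components of the induced subgraph that contain no target are discarded
#' (with a message); the result is scored as `sum(w) / sqrt(size)`, a
#' Z-score-style normalization that makes subnetworks of different sizes
#' comparable.
#'
#' @param model the solved `flow_model`
#' @param solution result of [solve_flow()]
#' @param threshold inclusion threshold on `x` (default 1e-6)
#' @return object of class `subnetwork_result`: `genes`, `edges` (induced),
#'   `targets`, `R_requested`, `objective`, `normalized_score`,
#'   `lp_integral`, `x` (selection values of the kept genes)
#' @export
extract_subnetwork <- function(model, solution, threshold = 1e-6) {
  stopifnot(inherits(model, "flow_model"))
  x <- solution$x
  genes <- names(x)[x > threshold]
  genes <- sort(union(genes, model$targets))
  arcs <- model$arcs[model$arcs[, 1] < model$arcs[, 2], , drop = FALSE]
  ga <- model$nodes[arcs[, 1]]
  gb <- model$nodes[arcs[, 2]]
  keep <- ga %in% genes & gb %in% genes
  ed <- data.frame(gene_a = ga[keep], gene_b = gb[keep],
                   stringsAsFactors = FALSE)
  # keep only components that touch a target
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = genes))
  comp <- igraph::components(g)
  with_target <- unique(comp$membership[model$targets])
  orphan <- genes[!(comp$membership[genes] %in% with_target)]
  if (length(orphan)) {
    message(length(orphan),
            " selected gene(s) in target-free components dropped")
    genes <- setdiff(genes, orphan)
    keep2 <- ed$gene_a %in% genes & ed$gene_b %in% genes
    ed <- ed[keep2, , drop = FALSE]
  }
  rownames(ed) <- NULL
  structure(list(
    genes = genes,
    edges = ed,
    targets = model$targets,
    R_requested = model$R,
    objective = solution$objective,
    normalized_score = sum(model$weights[genes]) / sqrt(length(genes)),
    lp_integral = isTRUE(solution$integral),
    x = solution$x[genes]),
    class = "subnetwork_result")
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat(sprintf(
    "subnetwork_result: %d genes (R = %d requested), score = %.4f%s\n",
    length(x$genes), x$R_requested, x$normalized_score,
    if (x$lp_integral) ", integral" else ", fractional"))
  invisible(x)
}

# deterministic BFS shortest path: at each level the parent with the
# lexicographically smallest symbol wins
lex_shortest_path <- function(adj, from, to) {
  if (from == to) return(from)
  parent <- stats::setNames(rep(NA_character_, length(adj)), names(adj))
  seen <- from
  frontier <- from
  while (length(frontier) && is.na(parent[to])) {
    nxt <- character(0)
    for (v in sort(frontier)) {
      for (u in adj[[v]]) {
        if (!(u %in% seen)) {
          parent[u] <- v
          seen <- c(seen, u)
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  if (is.na(parent[to])) return(NULL)
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  path
}

#' Bounds for the subnetwork-size grid
#'
#' The lower bound is the number of distinct genes on the shortest paths
#' between the drug targets (one deterministic shortest path per unordered
#' target pair, lexicographic tie-breaking); a single target gives 1.  The
#' upper bound is 10% of the network's node count (never below the lower
#' bound): a drug is assumed to affect only a limited part of the network.
#'
#' @param net a `molecular_network`
#' @param targets character vector of target genes present in `net`
#' @return list with integers `R_min`, `R_max`
#' @export
r_bounds <- function(net, targets) {
  stopifnot(inherits(net, "molecular_network"))
  targets <- unique(norm_symbol(targets))
  missing <- setdiff(targets, net$nodes)
  if (length(missing))
    stop("target(s) not in network: ", paste(missing, collapse = ", "))
  if (length(targets) == 1) {
    r_min <- 1L
  } else {
    adj <- adjacency_list(net)
    on_paths <- character(0)
    pairs <- utils::combn(sort(targets), 2)
    for (k in seq_len(ncol(pairs))) {
      p <- lex_shortest_path(adj, pairs[1, k], pairs[2, k])
      if (is.null(p))
        stop(sprintf("targets '%s' and '%s' are not connected",
                     pairs[1, k], pairs[2, k]))
      on_paths <- union(on_paths, p)
    }
    r_min <- length(on_paths)
  }
  list(R_min = as.integer(r_min),
       R_max = as.integer(max(r_min, floor(0.1 * length(net$nodes)))))
}

# named adjacency list with sorted neighbours
adjacency_list <- function(net) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (v in net$nodes) adj[[v]] <- character(0)
  if (nrow(net$edges)) {
    for (k in seq_len(nrow(net$edges))) {
      a <- net$edges$gene_a[k]
      b <- net$edges$gene_b[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, sort)
  }
  adj
}

#' Find the subnetwork affected by a treatment
#'
#' Scans the subnetwork size `R` over `{R_min, R_min + r_step, ..., R_max}`
#' (see [r_bounds()]), solves the relaxed flow model at each size, extracts
#' the selected genes and returns the subnetwork with the highest
#' normalized score `sum(w)/sqrt(size)`.  Ties go to the smaller gene set,
#' then to the lexicographically smaller one.
#'
#' @param net a `molecular_network`
#' @param weights named weight vector (see [build_flow_model()])
#' @param targets drug-target genes
#' @param r_step grid step for `R` (default 1)
#' @param threshold see [extract_subnetwork()]
#' @param exact solve exactly instead of the LP relaxation
#' @return the best `subnetwork_result`
#' @export
find_affected_subnetwork <- function(net, weights = NULL, targets,
                                     r_step = 1, threshold = 1e-6,
                                     exact = FALSE) {
  b <- r_bounds(net, targets)
  grid <- seq(b$R_min, b$R_max, by = max(1L, as.integer(r_step)))
  best <- NULL
  for (R in grid) {
    model <- build_flow_model(net, weights, targets, R)
    sub <- extract_subnetwork(model, solve_flow(model, exact = exact),
                              threshold)
    if (is.null(best) || better_subnetwork(sub, best)) best <- sub
  }
  best
}

# strict "is a better than b" under score, then size, then gene set
better_subnetwork <- function(a, b) {
  if (a$normalized_score != b$normalized_score)
    return(a$normalized_score > b$normalized_score)
  if (length(a$genes) != length(b$genes))
    return(length(a$genes) < length(b$genes))
  paste(a$genes, collapse = ",") < paste(b$genes, collapse = ",")
}

#' Exhaustive oracle for the flow model
#'
#' Enumerates every size-`R` node subset that contains all targets and is
#' connected once the dummy node is added (equivalently: every connected
#' component of the induced subgraph contains a target), and returns the
#' subset with the largest total weight.  Ties break lexicographically.
#' Intended as an independent test oracle; refuses networks above 16 nodes.
#'
#' @param net a `molecular_network`
#' @param weights named weight vector
#' @param targets target genes
#' @param R subset size
#' @return list with `genes`, `objective`, `feasible`; when no feasible
#'   subset exists, `feasible` is FALSE and `genes` is NULL
#' @export
brute_force_oracle <- function(net, weights = NULL, targets, R) {
  stopifnot(inherits(net, "molecular_network"))
  if (length(net$nodes) > 16)
    stop("brute_force_oracle limited to networks of at most 16 nodes")
  targets <- unique(norm_symbol(targets))
  stopifnot(all(targets %in% net$nodes), R >= length(targets),
            R <= length(net$nodes))
  if (is.null(weights)) weights <- net$weights
  w <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  if (!is.null(weights))
    w[intersect(names(weights), net$nodes)] <-
      weights[intersect(names(weights), net$nodes)]
  adj <- adjacency_list(net)
  rest <- setdiff(net$nodes, targets)
  k <- R - length(targets)
  cand <- if (k == 0) list(character(0))
          else utils::combn(rest, k, simplify = FALSE)
  best <- NULL
  for (extra in cand) {
    genes <- sort(c(targets, extra))
    if (!rooted_connected(genes, targets, adj)) next
    obj <- sum(w[genes])
    if (is.null(best) || obj > best$objective ||
        (obj == best$objective &&
         paste(genes, collapse = ",") < paste(best$genes, collapse = ","))) {
      best <- list(genes = genes, objective = obj, feasible = TRUE)
    }
  }
  if (is.null(best)) list(genes = NULL, objective = NA_real_,
                          feasible = FALSE)
  else best
}

# every component of the induced subgraph over `genes` contains a target
rooted_connected <- function(genes, targets, adj) {
  seen <- targets
  frontier <- targets
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- intersect(adj[[v]], genes)
      new <- setdiff(nb, seen)
      seen <- c(seen, new)
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  length(seen) == length(genes)
}
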