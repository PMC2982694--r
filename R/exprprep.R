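# Probe-level expression matrices -> per-drug gene-level ratio profiles.

#' Collapse probe-level values to gene-level values
#'
#' Two-step averaging.  Step 1: probes mapping to the same symbol string are
#' averaged into one value per string.  Symbol strings may be pseudo-symbols
#' combining several genes, written `"A /// B"`.  Step 2: the value of a
#' true gene is the mean over all symbol strings that equal it or contain it
#' as a `///`-separated token.
#'
#' @param probe_matrix numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns.
#' @param probe_gene_map data.frame with columns `probe`, `symbol`.  Probes
#'   without a mapping are dropped (count reported via `message`).
#' @return numeric matrix, genes x samples
#' @export
collapse_probes <- function(probe_matrix, probe_gene_map) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)),
            is.data.frame(probe_gene_map),
            all(c("probe", "symbol") %in% names(probe_gene_map)))
  if (ncol(probe_matrix) == 0) stop("probe matrix has zero samples")
  map <- stats::setNames(as.character(probe_gene_map$symbol),
                         as.character(probe_gene_map$probe))
  known <- rownames(probe_matrix) %in% names(map)
  if (any(!known))
    message(sum(!known), " unmapped probe(s) dropped")
  m <- probe_matrix[known, , drop = FALSE]
  if (nrow(m) == 0) stop("no mapped probes left")
  sym <- unname(map[rownames(m)])
  # step 1: mean per symbol string
  by_sym <- rowsum(m, group = sym) / as.vector(table(sym)[sort(unique(sym))])
  # step 2: mean over symbol strings containing each true gene as a token
  tokens <- strsplit(rownames(by_sym), "\\s*///\\s*")
  genes <- sort(unique(trimws(unlist(tokens))))
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in genes) {
    hit <- vapply(tokens, function(tk) g %in% trimws(tk), logical(1))
    out[g, ] <- colMeans(by_sym[hit, , drop = FALSE])
  }
  out
}

#' Filter a sample metadata table
#'
#' Applies the bookkeeping rules used before case/control aggregation:
#' batches named in `merge_batches` are relabeled (by default `"2a"` into
#' `"2"`); batches whose non-control samples carry exactly one distinct
#' perturbagen are removed outright; finally only samples from the
#' configured cell line are kept.
#'
#' @param meta data.frame with columns `sample_id`, `batch_id`, `cell_line`,
#'   `perturbagen` (drug name or `"CONTROL"`), `dose`, `control_ids`
#'   (semicolon-separated sample ids, empty for controls).
#' @param cell_line cell line to keep (default `"MCF7"`)
#' @param merge_batches named character vector, `old = new` batch relabels
#' @return filtered metadata data.frame
#' @export
filter_samples <- function(meta, cell_line = "MCF7",
                           merge_batches = c("2a" = "2")) {
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "batch_id", "cell_line", "perturbagen",
                  "dose", "control_ids") %in% names(meta)))
  bid <- as.character(meta$batch_id)
  hit <- bid %in% names(merge_batches)
  bid[hit] <- unname(merge_batches[bid[hit]])
  meta$batch_id <- bid
  # drop batches driven by a single perturbagen
  drugs_in_batch <- tapply(meta$perturbagen, meta$batch_id,
                           function(p) length(unique(p[p != "CONTROL"])))
  single <- names(drugs_in_batch)[drugs_in_batch == 1]
  meta <- meta[!(meta$batch_id %in% single), , drop = FALSE]
  meta <- meta[meta$cell_line == cell_line, , drop = FALSE]
  if (nrow(meta) == 0) message("filter_samples: no samples survive filtering")
  rownames(meta) <- NULL
  meta
}

# split a semicolon-separated control_ids field
split_ids <- function(x) {
  ids <- trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
  ids[nzchar(ids)]
}

#' Aggregate case and control expression for one drug/dose
#'
#' Within a batch, each case sample's controls are averaged into one merged
#' control; replicate cases of the same drug/dose are averaged; across
#' batches the per-batch case and control vectors are averaged again.
#'
#' @param gene_matrix genes x samples numeric matrix ([collapse_probes()])
#' @param meta filtered metadata ([filter_samples()])
#' @param drug perturbagen name
#' @param dose numeric dose; cases are matched on both drug and dose
#' @return list with numeric vectors `T` (case) and `C` (control), named by
#'   gene
#' @export
aggregate_case_control <- function(gene_matrix, meta, drug, dose) {
  cases <- meta[meta$perturbagen == drug & meta$dose == dose, , drop = FALSE]
  if (nrow(cases) == 0)
    stop(sprintf("no case samples for drug '%s' at dose %s", drug, dose))
  per_batch_T <- list()
  per_batch_C <- list()
  for (b in unique(cases$batch_id)) {
    cb <- cases[cases$batch_id == b, , drop = FALSE]
    t_mat <- gene_matrix[, cb$sample_id, drop = FALSE]
    c_means <- vapply(seq_len(nrow(cb)), function(k) {
      ctl <- split_ids(cb$control_ids[k])
      if (length(ctl) == 0)
        stop(sprintf("case '%s' (drug '%s') has no linked controls",
                     cb$sample_id[k], drug))
      missing <- setdiff(ctl, colnames(gene_matrix))
      if (length(missing))
        stop("unknown control sample(s): ", paste(missing, collapse = ", "))
      rowMeans(gene_matrix[, ctl, drop = FALSE])
    }, numeric(nrow(gene_matrix)))
    c_means <- matrix(c_means, nrow = nrow(gene_matrix),
                      dimnames = list(rownames(gene_matrix), NULL))
    per_batch_T[[b]] <- rowMeans(t_mat)
    per_batch_C[[b]] <- rowMeans(c_means)
  }
  list(T = rowMeans(do.call(cbind, per_batch_T)),
       C = rowMeans(do.call(cbind, per_batch_C)))
}

#' Case/control expression ratios
#'
#' Gene-wise ratio `T/C`.  Genes whose control (or case) value falls at or
#' below the floor `eps_c` are dropped, so the returned ratios are strictly
#' positive.
#'
#' @param T,C equal-length named numeric vectors over the same genes
#' @param eps_c positive floor guarding against division blow-ups
#' @return named numeric vector of ratios
#' @export
compute_ratios <- function(T, C, eps_c = 1e-6) {
  stopifnot(length(T) == length(C), identical(names(T), names(C)))
  bad <- C <= eps_c | T <= eps_c
  if (any(bad)) message(sum(bad), " gene(s) dropped at the expression floor")
  if (all(bad)) stop("all genes dropped: control values at or below floor")
  T[!bad] / C[!bad]
}

#' Differential-expression node weights
#'
#' Default weight of a gene is the absolute log2 fold change,
#' `w = |log2(T/C)|`: non-negative, zero exactly at ratio 1, and symmetric
#' under induction/repression (`w(r) = w(1/r)`).  Any alternative
#' non-negative function of the ratio can be plugged in.
#'
#' @param ratios strictly positive named numeric vector
#' @param weight_fn function ratio-vector -> weight-vector (default
#'   absolute log2)
#' @return named non-negative numeric vector of weights
#' @export
compute_weights <- function(ratios, weight_fn = NULL) {
  if (any(ratios <= 0) || anyNA(ratios))
    stop("ratios must be strictly positive")
  if (is.null(weight_fn)) weight_fn <- function(r) abs(log2(r))
  w <- weight_fn(ratios)
  if (any(w < 0)) stop("weight_fn produced negative weights")
  stats::setNames(as.numeric(w), names(ratios))
}

#' Build an expression profile object
#'
#' @param label treatment label (drug name or combination)
#' @param ratios strictly positive named ratio vector
#' @param weight_fn see [compute_weights()]
#' @return object of class `expr_profile` with `label`, `ratios`, `weights`
#' @export
expression_profile <- function(label, ratios, weight_fn = NULL) {
  structure(list(label = label, ratios = ratios,
                 weights = compute_weights(ratios, weight_fn)),
            class = "expr_profile")
}

#' @export
print.expr_profile <- function(x, ...) {
  cat(sprintf("expr_profile '%s': %d genes, max |log2 ratio| = %.3g\n",
              x$label, length(x$ratios), max(abs(log2(x$ratios)))))
  invisible(x)
}

#' Representative single-drug profile
#'
#' Computes one ratio profile per available dose of the drug and combines
#' them into one representative profile.  By default the representative
#' ratio of a gene is the mean of its per-dose ratios (over the doses where
#' the gene survives the expression floor); passing `dose` restricts to a
#' single dose instead.
#'
#' @param gene_matrix genes x samples matrix
#' @param meta filtered metadata
#' @param drug perturbagen name
#' @param dose optional single dose; NULL averages across doses
#' @param eps_c expression floor, see [compute_ratios()]
#' @param weight_fn see [compute_weights()]
#' @return an `expr_profile`
#' @export
drug_profile <- function(gene_matrix, meta, drug, dose = NULL,
                         eps_c = 1e-6, weight_fn = NULL) {
  doses <- if (is.null(dose)) {
    sort(unique(meta$dose[meta$perturbagen == drug]))
  } else dose
  if (length(doses) == 0)
    stop(sprintf("no samples for drug '%s'", drug))
  per_dose <- lapply(doses, function(d) {
    tc <- aggregate_case_control(gene_matrix, meta, drug, d)
    compute_ratios(tc$T, tc$C, eps_c = eps_c)
  })
  genes <- sort(unique(unlist(lapply(per_dose, names))))
  acc <- matrix(NA_real_, length(genes), length(per_dose),
                dimnames = list(genes, NULL))
  for (k in seq_along(per_dose)) acc[names(per_dose[[k]]), k] <- per_dose[[k]]
  ratios <- rowMeans(acc, na.rm = TRUE)
  expression_profile(drug, ratios, weight_fn)
}
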