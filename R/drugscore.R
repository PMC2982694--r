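# Efficacy vs side-effect scoring of affected subnetworks, and the
# combination-effectiveness verdict.

#' Efficacy of a treatment from its affected subnetwork
#'
#' Fraction of the background disease-gene weight captured by the
#' subnetwork: `sum_{SD} w / sum_{BD} w`, where `SD` are the disease genes
#' inside the subnetwork and `BD` the disease genes of the whole background
#' network.  Returns 0 (with a message) when no background disease gene
#' carries weight.
#'
#' @param subnet_genes genes of the affected subnetwork
#' @param weights named weight vector of the treatment being scored; genes
#'   absent from it weigh 0
#' @param disease_genes disease-gene set (non-empty)
#' @param background_genes genes of the background network
#' @return efficacy in `[0, 1]`
#' @export
efficacy_score <- function(subnet_genes, weights, disease_genes,
                           background_genes) {
  if (length(disease_genes) == 0) stop("disease gene set is empty")
  bd <- intersect(background_genes, disease_genes)
  sd <- intersect(subnet_genes, bd)
  denom <- sum_weights(bd, weights)
  if (denom == 0) {
    message("efficacy_score: disease genes carry no weight in background")
    return(0)
  }
  sum_weights(sd, weights) / denom
}

#' Side-effect liability of a treatment
#'
#' Fraction of the background essential-gene weight captured by the
#' subnetwork, counting only "innocent" essential genes, i.e. essential
#' genes with no relation to the disease: `sum_{ED} w / sum_{EB} w` with
#' `ED = subnet ∩ essential \\ disease` and `EB` the same intersection
#' over the background.  Returns 0 when `EB` carries no weight.
#'
#' @inheritParams efficacy_score
#' @param essential_genes essential-gene set (mouse-lethal orthologs or
#'   similar)
#' @return side-effect score in `[0, 1]`
#' @export
side_effect_score <- function(subnet_genes, weights, essential_genes,
                              disease_genes, background_genes) {
  eb <- setdiff(intersect(background_genes, essential_genes), disease_genes)
  ed <- intersect(subnet_genes, eb)
  denom <- sum_weights(eb, weights)
  if (denom == 0) return(0)
  sum_weights(ed, weights) / denom
}

sum_weights <- function(genes, weights) {
  w <- weights[genes]
  sum(w[!is.na(w)])
}

#' Balanced treatment score
#'
#' `S_eff = lambda * efficacy - (1 - lambda) * side_effect`: `lambda = 1`
#' scores efficacy alone, `lambda = 0` scores (negated) side-effect alone.
#'
#' @param efficacy efficacy term in `[0, 1]`
#' @param side_effect side-effect term in `[0, 1]`
#' @param lambda trade-off parameter in `[0, 1]`
#' @return scalar score in `[-1, 1]`
#' @export
s_eff <- function(efficacy, side_effect, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  lambda * efficacy - (1 - lambda) * side_effect
}

#' Score scan over the efficacy/side-effect trade-off
#'
#' Evaluates [s_eff()] on a regular lambda grid from 0 to 1.  Because the
#' score is linear in lambda with slope `efficacy + side_effect >= 0`, the
#' scan is non-decreasing.
#'
#' @inheritParams s_eff
#' @param grid_step grid spacing; must divide 1 (default 0.05, 21 rows)
#' @return data.frame with columns `lambda`, `s_eff`
#' @export
lambda_scan <- function(efficacy, side_effect, grid_step = 0.05) {
  n_steps <- 1 / grid_step
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("grid_step must divide 1")
  lam <- seq(0, 1, length.out = round(n_steps) + 1)
  data.frame(lambda = lam,
             s_eff = vapply(lam, function(l) s_eff(efficacy, side_effect, l),
                            0))
}

#' Score a subnetwork for one treatment
#'
#' @param subnet a `subnetwork_result` (or a plain character vector of
#'   genes)
#' @inheritParams side_effect_score
#' @param lambda trade-off parameter
#' @return object of class `score_breakdown` with `lambda`, `efficacy`,
#'   `side_effect`, `s_eff` and the gene sets `SD`, `BD`, `ED` used
#' @export
score_subnetwork <- function(subnet, weights, disease_genes, essential_genes,
                             background_genes, lambda = 0.5) {
  genes <- if (inherits(subnet, "subnetwork_result")) subnet$genes
           else subnet
  bd <- intersect(background_genes, disease_genes)
  eff <- efficacy_score(genes, weights, disease_genes, background_genes)
  side <- side_effect_score(genes, weights, essential_genes, disease_genes,
                            background_genes)
  structure(list(
    lambda = lambda, efficacy = eff, side_effect = side,
    s_eff = s_eff(eff, side, lambda),
    SD = sort(intersect(genes, bd)),
    BD = sort(bd),
    ED = sort(intersect(genes, setdiff(intersect(background_genes,
                                                 essential_genes),
                                       disease_genes)))),
    class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "score_breakdown: S_eff = %.4f (lambda = %.2f, efficacy = %.4f, side_effect = %.4f)\n",
    x$s_eff, x$lambda, x$efficacy, x$side_effect))
  invisible(x)
}

#' Rank drug combinations against their members
#'
#' For every size-`order` subset of the supplied drugs: predict the
#' combination's expression profile from the member profiles, take the
#' union of the member targets, extract the affected subnetwork of the
#' combination and of every member (each member with its own profile and
#' targets), and score everything with the balanced score at the given
#' `lambda`.  A combination is called effective when its score strictly
#' exceeds the score of every member.  Drugs whose targets are missing
#' from the background network are excluded up front (with a message).
#'
#' @param profiles named list of `expr_profile` objects, one per drug
#' @param targets_map named list: drug -> character vector of target genes
#' @param net background `molecular_network`
#' @param disease_genes,essential_genes gene sets for scoring
#' @param order combination size (default 2)
#' @param lambda trade-off parameter (default 0.5)
#' @param mode ratio-combination mode, see [combine_ratios()]
#' @param r_step grid step for the subnetwork-size scan
#' @param threshold see [extract_subnetwork()]
#' @return data.frame of verdicts (one row per combination, sorted by
#'   combination score, descending) with columns `combo_label`,
#'   `combo_score`, `member_scores` (comma-separated), `effective`;
#'   per-treatment details are attached as attributes `breakdowns` and
#'   `subnetworks`
#' @export
rank_combinations <- function(profiles, targets_map, net, disease_genes,
                              essential_genes, order = 2, lambda = 0.5,
                              mode = c("additive", "saturating"),
                              r_step = 1, threshold = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(length(profiles) >= order, !is.null(names(profiles)),
            all(names(profiles) %in% names(targets_map)))
  drugs <- names(profiles)
  usable <- vapply(drugs, function(d) {
    all(norm_symbol(targets_map[[d]]) %in% net$nodes)
  }, TRUE)
  if (any(!usable))
    message("drug(s) excluded, target(s) outside the background network: ",
            paste(drugs[!usable], collapse = ", "))
  drugs <- drugs[usable]
  if (length(drugs) < order)
    stop("fewer usable drugs than the combination order")
  score_one <- function(profile, targets) {
    sub <- find_affected_subnetwork(net, profile$weights, targets,
                                    r_step = r_step, threshold = threshold)
    list(subnet = sub,
         breakdown = score_subnetwork(sub, profile$weights, disease_genes,
                                      essential_genes, net$nodes, lambda))
  }
  members <- lapply(drugs, function(d) {
    score_one(profiles[[d]], norm_symbol(targets_map[[d]]))
  })
  names(members) <- drugs
  combos <- utils::combn(drugs, order, simplify = FALSE)
  rows <- vector("list", length(combos))
  breakdowns <- list()
  subnets <- list()
  for (k in seq_along(combos)) {
    cd <- combos[[k]]
    pred <- predict_profile(profiles[cd], mode = mode)
    tg <- sort(unique(unlist(lapply(cd, function(d)
      norm_symbol(targets_map[[d]])))))
    combo <- score_one(pred, tg)
    member_scores <- vapply(cd, function(d) members[[d]]$breakdown$s_eff, 0)
    rows[[k]] <- data.frame(
      combo_label = pred$label,
      combo_score = combo$breakdown$s_eff,
      member_scores = paste(sprintf("%.6f", member_scores), collapse = ","),
      effective = combo$breakdown$s_eff > max(member_scores),
      stringsAsFactors = FALSE)
    breakdowns[[pred$label]] <- combo$breakdown
    subnets[[pred$label]] <- combo$subnet
  }
  for (d in drugs) {
    breakdowns[[d]] <- members[[d]]$breakdown
    subnets[[d]] <- members[[d]]$subnet
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$combo_score, out$combo_label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "breakdowns") <- breakdowns
  attr(out, "subnetworks") <- subnets
  out
}
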