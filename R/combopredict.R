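# Predict a combination drug's expression-ratio profile from its members.

#' Combine member ratios for one gene
#'
#' First-order (Taylor) additive rule: the combination's case/control ratio
#' is `F = 1 + sum_j (r_j - 1)`, i.e. one plus the summed deviations of the
#' member ratios from the no-perturbation baseline.  In `"saturating"` mode
#' a nonlinear correction damps co-directional effects: when every non-zero
#' deviation shares one sign, `F = 1 + s * max_j |r_j - 1|` (`s` the shared
#' sign) instead of the sum, so agreeing members cannot overshoot the most
#' extreme single member.  Predicted ratios below the floor `eps_f` are
#' clipped to it (the additive rule can go negative when several members
#' strongly repress the same gene) and flagged.
#'
#' @param member_ratios numeric vector of strictly positive member ratios
#'   for one gene (length >= 1)
#' @param mode `"additive"` or `"saturating"`
#' @param eps_f positive clipping floor (default 0.01)
#' @return list with `ratio` (positive scalar) and `mode_used` (one of
#'   `"additive"`, `"saturated"`, `"clipped"`)
#' @export
combine_ratios <- function(member_ratios, mode = c("additive", "saturating"),
                           eps_f = 0.01) {
  mode <- match.arg(mode)
  if (length(member_ratios) == 0) stop("at least one member ratio required")
  if (any(member_ratios <= 0) || anyNA(member_ratios))
    stop("member ratios must be strictly positive")
  res <- combine_ratio_matrix(matrix(member_ratios, nrow = 1), mode, eps_f)
  list(ratio = unname(res$ratio), mode_used = unname(res$mode_used))
}

# vectorised core: genes x members matrix of ratios
combine_ratio_matrix <- function(rmat, mode, eps_f) {
  dev <- rmat - 1
  f <- 1 + rowSums(dev)
  used <- rep("additive", nrow(rmat))
  if (mode == "saturating") {
    pos <- rowSums(dev > 0)
    neg <- rowSums(dev < 0)
    sat <- (pos == 0 | neg == 0) & (pos + neg > 0)  # zero devs are neutral
    if (any(sat)) {
      mx <- apply(abs(dev[sat, , drop = FALSE]), 1, max)
      s <- ifelse(pos[sat] > 0, 1, -1)
      f[sat] <- 1 + s * mx
      used[sat] <- "saturated"
    }
  }
  clip <- f < eps_f
  f[clip] <- eps_f
  used[clip] <- "clipped"
  list(ratio = f, mode_used = used)
}

#' Predict the expression profile of a drug combination
#'
#' Applies [combine_ratios()] gene-by-gene over the intersection of the
#' member profiles' gene sets and recomputes weights from the predicted
#' ratios.  A single member is returned as its own (trivial) prediction.
#'
#' @param members list of `expr_profile` objects (length >= 1)
#' @param mode `"additive"` or `"saturating"`
#' @param eps_f clipping floor, see [combine_ratios()]
#' @param weight_fn see [compute_weights()]
#' @return object of class `combo_prediction` (an `expr_profile` with extra
#'   fields `member_labels` and `mode_used`, a per-gene character vector)
#' @export
predict_profile <- function(members, mode = c("additive", "saturating"),
                            eps_f = 0.01, weight_fn = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(members) >= 1,
            all(vapply(members, inherits, TRUE, "expr_profile")))
  genes <- Reduce(intersect, lapply(members, function(p) names(p$ratios)))
  if (length(genes) == 0) stop("member profiles share no genes")
  genes <- sort(genes)
  rmat <- vapply(members, function(p) p$ratios[genes],
                 numeric(length(genes)))
  if (is.null(dim(rmat))) rmat <- matrix(rmat, nrow = length(genes))
  res <- combine_ratio_matrix(rmat, mode, eps_f)
  labels <- vapply(members, function(p) p$label, "")
  n_clip <- sum(res$mode_used == "clipped")
  if (n_clip > 0)
    message(sprintf("predict_profile(%s): %d gene(s) clipped at %.3g",
                    paste(labels, collapse = "&"), n_clip, eps_f))
  prof <- expression_profile(paste(labels, collapse = "&"),
                             stats::setNames(res$ratio, genes), weight_fn)
  prof$member_labels <- labels
  prof$mode_used <- stats::setNames(res$mode_used, genes)
  class(prof) <- c("combo_prediction", class(prof))
  prof
}
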