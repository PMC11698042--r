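# Segmentation evaluation metrics.
#
# Instance matching follows the optimal one-to-one assignment
# convention: pairwise IoU over intersecting ground-truth/prediction
# pairs, Hungarian assignment maximizing total IoU, and a match counted
# as a true positive when its IoU reaches the threshold tau. Count
# accuracy is reported as the percentage cell count error
# 100 * |N_gt - N_pred| / N_gt. Partition quality over the ground-truth
# foreground is scored by the Adapted Rand error and the split/merge
# components of the variation of information (in bits).

# IoU matrix (rows = gt labels, cols = pred labels) and the optimal
# assignment, computed once and reused across thresholds
.instance_assignment <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) .eq_stop("label maps differ in shape")
  ng <- max(gt, 0L)
  np <- max(pred, 0L)
  if (ng == 0 || np == 0)
    return(list(ng = n_objects(gt), np = n_objects(pred),
                pairs = cbind(integer(0), integer(0)), iou = numeric(0)))
  ag <- tabulate(gt[gt > 0L], nbins = ng)
  ap <- tabulate(pred[pred > 0L], nbins = np)
  sel <- gt > 0L & pred > 0L
  iou_mat <- matrix(0, ng, np)
  if (any(sel)) {
    inter <- table(gt = gt[sel], pred = pred[sel])
    gi <- as.integer(rownames(inter))
    pj <- as.integer(colnames(inter))
    for (a in seq_along(gi))
      for (b in seq_along(pj)) {
        n <- inter[a, b]
        if (n > 0)
          iou_mat[gi[a], pj[b]] <- n / (ag[gi[a]] + ap[pj[b]] - n)
      }
  }
  # maximize total IoU via the Hungarian algorithm on a square padding
  nn <- max(ng, np)
  cost <- matrix(1, nn, nn)
  cost[seq_len(ng), seq_len(np)] <- 1 - iou_mat
  sol <- clue::solve_LSAP(cost)
  gi <- seq_len(nn)
  pj <- as.integer(sol)
  keep <- gi <= ng & pj <= np
  gi <- gi[keep]; pj <- pj[keep]
  iou <- iou_mat[cbind(gi, pj)]
  pos <- iou > 0
  list(ng = sum(ag > 0), np = sum(ap > 0),
       pairs = cbind(gt = gi[pos], pred = pj[pos]), iou = iou[pos])
}

.match_from_assignment <- function(asg, tau) {
  tp <- sum(asg$iou >= tau)
  fp <- asg$np - tp
  fn <- asg$ng - tp
  precision <- if (asg$np > 0) tp / asg$np else 0
  recall <- if (asg$ng > 0) tp / asg$ng else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  list(tau = tau, TP = tp, FP = fp, FN = fn,
       precision = precision, recall = recall, f1 = f1,
       mean_matched_iou = if (tp > 0) mean(asg$iou[asg$iou >= tau])
                          else NA_real_)
}

#' Match instances between two label maps at an IoU threshold
#'
#' @param gt,pred label maps ([label_map] or integer matrices) of the
#'   same shape.
#' @param tau IoU threshold in `(0, 1)`.
#' @return list with `tau`, `TP`, `FP`, `FN`, `precision`, `recall`,
#'   `f1` and `mean_matched_iou`.
#' @export
match_instances <- function(gt, pred, tau = 0.5) {
  if (inherits(gt, "label_map")) gt <- gt$labels
  if (inherits(pred, "label_map")) pred <- pred$labels
  if (!(tau > 0 && tau < 1)) .eq_stop("'tau' must be in (0, 1)")
  .match_from_assignment(.instance_assignment(gt, pred), tau)
}

#' F1 over a sweep of IoU thresholds
#'
#' The assignment is computed once; thresholds are applied to the fixed
#' matching, so F1 is non-increasing in tau.
#'
#' @param gt,pred label maps of the same shape.
#' @param taus IoU thresholds (default 0.1 to 0.9 in steps of 0.05).
#' @return `data.frame` with one row per tau: TP, FP, FN, precision,
#'   recall, f1, mean_matched_iou.
#' @export
f1_curve <- function(gt, pred, taus = seq(0.1, 0.9, by = 0.05)) {
  if (inherits(gt, "label_map")) gt <- gt$labels
  if (inherits(pred, "label_map")) pred <- pred$labels
  asg <- .instance_assignment(gt, pred)
  rows <- lapply(taus, function(t) .match_from_assignment(asg, t))
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Percentage cell count error
#'
#' `100 * |n_gt - n_pred| / n_gt`: the headline accuracy measure for
#' cell counting, symmetric in the direction of the error.
#'
#' @param n_gt ground-truth count (> 0).
#' @param n_pred predicted count.
#' @return percentage error.
#' @export
percent_count_error <- function(n_gt, n_pred) {
  if (any(n_gt <= 0)) .eq_stop("'n_gt' must be positive")
  100 * abs(n_gt - n_pred) / n_gt
}

#' Intersection over union of two binary masks
#'
#' `|a AND b| / |a OR b|`; two empty masks score 1, exactly one empty
#' mask scores 0.
#'
#' @param a,b logical matrices of the same shape.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) .eq_stop("masks differ in shape")
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

#' Adapted Rand error and variation of information
#'
#' Computed over the pixels that are foreground in the ground truth
#' (background excluded). The Adapted Rand error is 1 minus the F-score
#' of the pair-counting contingency between the two partitions;
#' `voi_split = H(gt | pred)` and `voi_merge = H(pred | gt)` in bits, so
#' a prediction that merges ground-truth objects has positive
#' `voi_split` and one that splits them has positive `voi_merge`. All
#' three are zero exactly when the partitions agree up to a label
#' permutation.
#'
#' @param gt,pred label maps of the same shape; `gt` must contain
#'   foreground.
#' @return list with `adapted_rand_error`, `voi_split`, `voi_merge`.
#' @export
partition_metrics <- function(gt, pred) {
  if (inherits(gt, "label_map")) gt <- gt$labels
  if (inherits(pred, "label_map")) pred <- pred$labels
  if (!all(dim(gt) == dim(pred))) .eq_stop("label maps differ in shape")
  sel <- gt > 0L
  if (!any(sel)) .eq_stop("ground truth is entirely background")
  g <- gt[sel]
  p <- pred[sel]
  n <- length(g)
  cont <- table(g, p)
  nij <- as.numeric(cont)
  ai <- rowSums(cont)
  bj <- colSums(cont)
  # Adapted Rand: F-score of pair counts (sums of squares convention)
  s_ij <- sum(nij^2)
  prec <- s_ij / sum(bj^2)
  rec <- s_ij / sum(ai^2)
  are <- 1 - 2 * prec * rec / (prec + rec)
  # conditional entropies, base 2
  pj_mat <- nij / n
  h <- function(x) ifelse(x > 0, x * log2(x), 0)
  h_joint <- -sum(h(pj_mat))
  h_g <- -sum(h(ai / n))
  h_p <- -sum(h(bj / n))
  list(adapted_rand_error = are,
       voi_split = h_joint - h_p,  # H(gt | pred)
       voi_merge = h_joint - h_g)  # H(pred | gt)
}
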