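#' Intersection over union of two masks
#'
#' `|A intersect B| / |A union B|`; two empty masks are defined to have
#' IoU 1 (vacuous perfection).
#'
#' @param pred,gt binary masks of the same shape.
#' @return fraction in `[0, 1]`.
#' @export
iou <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("mask shapes differ")
  inter <- sum(pred == 1L & gt == 1L)
  uni <- sum(pred == 1L | gt == 1L)
  if (uni == 0) return(1)
  inter / uni
}

#' Amodal segmentation metrics
#'
#' * `miou` — mean IoU of predicted vs ground-truth amodal masks over
#'   instances.
#' * `p_acc` — pixel accuracy: correctly classified pixels over all
#'   pixels, pooled over instances.
#' * `inv_miou` — mean IoU restricted to the invisible regions
#'   (`amodal AND NOT modal`), over instances that actually have a
#'   non-empty invisible region; `NA` when no instance is occluded.
#'
#' @param preds list of predicted amodal masks.
#' @param gts list of ground-truth amodal masks.
#' @param modals list of modal masks (for the invisible regions).
#' @return list with `miou`, `p_acc`, `inv_miou`, and the counts of
#'   instances evaluated.
#' @export
segmentation_metrics <- function(preds, gts, modals) {
  stopifnot(length(preds) == length(gts), length(gts) == length(modals))
  n <- length(preds)
  ious <- numeric(n)
  inv_ious <- numeric(0)
  correct <- 0; total <- 0
  for (i in seq_len(n)) {
    ious[i] <- iou(preds[[i]], gts[[i]])
    correct <- correct + sum(preds[[i]] == gts[[i]])
    total <- total + length(gts[[i]])
    gt_inv <- as_mask(gts[[i]] * (1L - modals[[i]]))
    if (sum(gt_inv) > 0) {
      pred_inv <- as_mask(preds[[i]] * (1L - modals[[i]]))
      inv_ious <- c(inv_ious, iou(pred_inv, gt_inv))
    }
  }
  list(miou = if (n > 0) mean(ious) else NA_real_,
       p_acc = if (total > 0) correct / total else NA_real_,
       inv_miou = if (length(inv_ious) > 0) mean(inv_ious) else NA_real_,
       n_instances = n, n_occluded = length(inv_ious))
}

#' Occlusion-order accuracies
#'
#' * `op_acc` — occlusion pairwise accuracy: among ordered pairs the
#'   prediction marks as occluding (`T_pred = 1`), the fraction whose
#'   ground truth also marks occluding,
#'   `sum(O == 1 & O_pred == 1) / sum(O_pred == 1)`. `NA` when nothing
#'   is predicted occluding.
#' * `ap_acc` — all-pair accuracy: the fraction of unordered pairs
#'   whose ternary relation (-1/0/1) matches the ground truth.
#' * `aop` — `op_acc` restricted to pairs whose two instances both have
#'   predicted amodal masks with IoU >= `tau` against ground truth
#'   (requires `pred_masks`/`gt_masks`).
#'
#' @param pred_graph,gt_graph `occlusion_graph`s over the same
#'   instances.
#' @param pred_masks,gt_masks optional lists of amodal masks for the
#'   IoU-validity filter.
#' @param tau IoU validity threshold (default 0.5).
#' @return list with `op_acc`, `ap_acc`, `aop`.
#' @export
order_metrics <- function(pred_graph, gt_graph, pred_masks = NULL,
                          gt_masks = NULL, tau = 0.5) {
  Tp <- pred_graph$T; Tg <- gt_graph$T
  stopifnot(all(dim(Tp) == dim(Tg)))
  n <- nrow(Tp)
  num <- 0; den <- 0; match <- 0; tot <- 0
  valid <- rep(TRUE, n)
  if (!is.null(pred_masks) && !is.null(gt_masks)) {
    valid <- vapply(seq_len(n), function(i)
      iou(pred_masks[[i]], gt_masks[[i]]) >= tau, logical(1))
  }
  aop_num <- 0; aop_den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (Tp[i, j] == 1L) {
      den <- den + 1
      if (Tg[i, j] == 1L) num <- num + 1
      if (valid[i] && valid[j]) {
        aop_den <- aop_den + 1
        if (Tg[i, j] == 1L) aop_num <- aop_num + 1
      }
    }
    if (j > i) {
      tot <- tot + 1
      if (Tp[i, j] == Tg[i, j]) match <- match + 1
    }
  }
  list(op_acc = if (den > 0) num / den else NA_real_,
       ap_acc = if (tot > 0) match / tot else NA_real_,
       aop = if (aop_den > 0) aop_num / aop_den else NA_real_)
}

#' Visibility ratio of an instance
#'
#' The ratio of visible pixels (modal mask area) to the total pixels of
#' the instance (amodal mask area) — the quantity used to profile how
#' exposed each fruit is.
#'
#' @param modal binary modal mask, a subset of `amodal`.
#' @param amodal non-empty binary amodal mask.
#' @return fraction in `(0, 1]`.
#' @export
visibility_ratio <- function(modal, amodal) {
  if (sum(amodal) == 0) stop("amodal mask is empty")
  sum(modal) / sum(amodal)
}

#' Single-category mask average precision
#'
#' Greedy score-ordered matching: predictions are visited in decreasing
#' score order (ties broken by instance index) and matched to the free
#' ground-truth mask of highest IoU, provided that IoU reaches the
#' threshold. AP at each threshold is the area under the interpolated
#' precision-recall curve (precision envelope). `AR@k` is the recall
#' attained with at most `k` detections per scene, averaged over the
#' thresholds.
#'
#' @param preds list of predicted masks.
#' @param scores numeric prediction confidences (same length).
#' @param gts list of ground-truth masks.
#' @param iou_thresholds IoU thresholds (default `c(0.5, 0.75)`).
#' @param k detection cap for `AR@k` (default 10).
#' @return list with `ap` (named per threshold), `mean_ap`, `ar`.
#' @export
mask_ap <- function(preds, scores, gts, iou_thresholds = c(0.5, 0.75),
                    k = 10L) {
  stopifnot(length(preds) == length(scores))
  np <- length(preds); ng <- length(gts)
  ord <- order(-scores, seq_len(np))
  iou_mat <- matrix(0, np, max(1, ng))
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    iou_mat[i, j] <- iou(preds[[i]], gts[[j]])
  }
  ap <- numeric(length(iou_thresholds))
  names(ap) <- sprintf("AP@%.2f", iou_thresholds)
  recalls_at_k <- numeric(length(iou_thresholds))
  for (t in seq_along(iou_thresholds)) {
    tau <- iou_thresholds[t]
    taken <- rep(FALSE, max(1, ng))
    tp <- numeric(np)
    for (r in seq_len(np)) {
      i <- ord[r]
      best <- 0; bj <- 0
      for (j in seq_len(ng)) {
        if (!taken[j] && iou_mat[i, j] >= tau && iou_mat[i, j] > best) {
          best <- iou_mat[i, j]; bj <- j
        }
      }
      if (bj > 0) { taken[bj] <- TRUE; tp[r] <- 1 }
    }
    if (ng == 0) { ap[t] <- 0; next }
    cum_tp <- cumsum(tp)
    prec <- cum_tp / seq_len(np)
    rec <- cum_tp / ng
    # precision envelope, all-point interpolation
    if (np > 0) {
      env <- rev(cummax(rev(prec)))
      r_prev <- 0; a <- 0
      for (r in seq_len(np)) {
        a <- a + (rec[r] - r_prev) * env[r]
        r_prev <- rec[r]
      }
      ap[t] <- a
    } else {
      ap[t] <- 0
    }
    recalls_at_k[t] <- if (np == 0) 0 else
      cum_tp[min(np, k)] / ng
  }
  list(ap = ap, mean_ap = mean(ap), ar = mean(recalls_at_k))
}
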