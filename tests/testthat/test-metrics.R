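test_that("IoU basics: identity, disjoint, pixel enumeration, conventions", {
  a <- disk_mask(16, 8, 8, 5)
  expect_equal(iou(a, a), 1)
  b <- matrix(0L, 16, 16); b[1:2, 1:2] <- 1L
  c <- matrix(0L, 16, 16); c[10:12, 10:12] <- 1L
  expect_equal(iou(b, c), 0)
  # {(0,0),(0,1)} vs {(0,1),(0,2)} -> 1/3
  p <- matrix(0L, 3, 3); p[1, 1:2] <- 1L
  q <- matrix(0L, 3, 3); q[1, 2:3] <- 1L
  expect_equal(iou(p, q), 1 / 3)
  expect_equal(iou(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_error(iou(matrix(0L, 3, 3), matrix(0L, 4, 4)), "differ")
  set.seed(80)
  for (k in 1:30) {
    x <- random_mask(10, 10); y <- random_mask(10, 10)
    expect_equal(iou(x, y), iou(y, x))
    expect_gte(iou(x, y), 0); expect_lte(iou(x, y), 1)
  }
})

test_that("segmentation metrics combine IoU, pixel accuracy and invisible IoU", {
  a <- disk_mask(32, 16, 16, 8)
  m <- as_mask(a * (1L - disk_mask(32, 16, 24, 8)))
  # perfect predictions
  s <- segmentation_metrics(list(a, a), list(a, a), list(m, a))
  expect_equal(s$miou, 1); expect_equal(s$p_acc, 1)
  expect_equal(s$inv_miou, 1)
  expect_equal(s$n_occluded, 1)
  # no completion at all: the occluded instance's inv-IoU is 0
  s2 <- segmentation_metrics(list(m), list(a), list(m))
  expect_equal(s2$inv_miou, 0)
  # two instances with IoUs 0.5 and 1.0 average to 0.75
  half <- a; half[seq(1, 32, 2), ] <- 0L
  built <- iou(half, a)
  s3 <- segmentation_metrics(list(half, a), list(a, a), list(a, a))
  expect_equal(s3$miou, (built + 1) / 2)
  # nothing occluded: inv-mIoU reported absent
  s4 <- segmentation_metrics(list(a), list(a), list(a))
  expect_true(is.na(s4$inv_miou))
})

test_that("order metrics match the printed formula and brute enumeration", {
  g <- function(T) structure(list(T = T, instance_ids = seq_len(nrow(T))),
                             class = "occlusion_graph")
  # GT pairs {(1,2):1, (2,3):1}; prediction gets (1,2) right and (2,3)
  # backwards -> numerator 1, denominator 2
  Tg <- matrix(0L, 3, 3); Tg[1, 2] <- 1L; Tg[2, 1] <- -1L
  Tg[2, 3] <- 1L; Tg[3, 2] <- -1L
  Tp <- matrix(0L, 3, 3); Tp[1, 2] <- 1L; Tp[2, 1] <- -1L
  Tp[3, 2] <- 1L; Tp[2, 3] <- -1L
  om <- order_metrics(g(Tp), g(Tg))
  expect_equal(om$op_acc, 0.5)
  expect_equal(om$ap_acc, 2 / 3)  # pairs (1,2) and (1,3) match, (2,3) not
  # perfect prediction
  om2 <- order_metrics(g(Tg), g(Tg))
  expect_equal(om2$op_acc, 1); expect_equal(om2$ap_acc, 1)
  # brute-force enumeration oracle on random antisymmetric graphs
  set.seed(81)
  for (k in 1:100) {
    n <- sample(2:6, 1)
    mk <- function() {
      T <- matrix(0L, n, n)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        v <- sample(c(-1L, 0L, 1L), 1)
        T[i, j] <- v; T[j, i] <- -v
      }
      T
    }
    Ta <- mk(); Tb <- mk()
    om3 <- order_metrics(g(Ta), g(Tb))
    den <- 0; num <- 0; match <- 0; tot <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      if (Ta[i, j] == 1L) {
        den <- den + 1
        if (Tb[i, j] == 1L) num <- num + 1
      }
    }
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      tot <- tot + 1
      if (Ta[i, j] == Tb[i, j]) match <- match + 1
    }
    if (den > 0) expect_equal(om3$op_acc, num / den) else
      expect_true(is.na(om3$op_acc))
    expect_equal(om3$ap_acc, match / tot)
  }
})

test_that("the IoU-validity filter restricts AOP to well-segmented pairs", {
  g <- function(T) structure(list(T = T, instance_ids = seq_len(nrow(T))),
                             class = "occlusion_graph")
  Tg <- matrix(0L, 2, 2); Tg[1, 2] <- 1L; Tg[2, 1] <- -1L
  a <- disk_mask(16, 8, 8, 5)
  bad <- matrix(0L, 16, 16); bad[1, 1] <- 1L
  om <- order_metrics(g(Tg), g(Tg), pred_masks = list(a, bad),
                      gt_masks = list(a, a), tau = 0.5)
  expect_equal(om$op_acc, 1)
  expect_true(is.na(om$aop))  # instance 2 fails the validity filter
  om2 <- order_metrics(g(Tg), g(Tg), pred_masks = list(a, a),
                       gt_masks = list(a, a), tau = 0.5)
  expect_equal(om2$aop, 1)
})

test_that("visibility ratio is the modal/amodal pixel quotient", {
  a <- disk_mask(24, 12, 12, 9)
  expect_equal(visibility_ratio(a, a), 1)
  m <- a; m[, 13:24] <- 0L
  expect_equal(visibility_ratio(m, a), sum(m) / sum(a))
  expect_error(visibility_ratio(m, matrix(0L, 24, 24)), "empty")
  set.seed(82)
  for (k in 1:100) {
    amodal <- random_mask(8, 8, 0.7)
    if (sum(amodal) == 0) next
    modal <- as_mask(amodal * random_mask(8, 8, 0.6))
    expect_equal(visibility_ratio(modal, amodal),
                 sum(modal) / sum(amodal))
  }
})

test_that("mask AP matches the definitional cases", {
  gts <- list(disk_mask(32, 10, 10, 6), disk_mask(32, 22, 22, 6))
  # predictions identical to ground truth: AP 1 everywhere
  r <- mask_ap(gts, c(0.9, 0.8), gts)
  expect_equal(unname(r$ap), c(1, 1))
  expect_equal(r$mean_ap, 1)
  # one prediction with IoU ~0.6 against a single GT: AP@0.5 = 1, @0.75 = 0
  gt <- disk_mask(32, 16, 16, 8)
  pred <- mask_shift(gt, 0, 4)
  expect_gt(iou(pred, gt), 0.5); expect_lt(iou(pred, gt), 0.75)
  r2 <- mask_ap(list(pred), 1, list(gt))
  expect_equal(unname(r2$ap), c(1, 0))
  # empty ground truth with predictions: AP 0
  r3 <- mask_ap(list(pred), 1, list())
  expect_equal(unname(r3$ap), c(0, 0))
})

test_that("mask AP agrees with an independently coded PR evaluation", {
  # independent oracle: recompute greedy matching and the interpolated
  # PR area with separate code, over random scenes of up to 4 instances
  ap_oracle <- function(preds, scores, gts, tau) {
    ord <- order(-scores, seq_along(preds))
    free <- rep(TRUE, length(gts))
    tp <- integer(length(preds))
    for (r in seq_along(ord)) {
      i <- ord[r]
      ious <- vapply(seq_along(gts), function(j)
        if (free[j]) iou(preds[[i]], gts[[j]]) else -1, numeric(1))
      if (length(ious) && max(ious) >= tau) {
        j <- which.max(ious)
        free[j] <- FALSE
        tp[r] <- 1L
      }
    }
    if (length(gts) == 0) return(0)
    rec <- cumsum(tp) / length(gts)
    prec <- cumsum(tp) / seq_along(tp)
    a <- 0; rp <- 0
    for (r in seq_along(tp)) {
      p_at <- max(prec[r:length(prec)])
      a <- a + (rec[r] - rp) * p_at
      rp <- rec[r]
    }
    a
  }
  set.seed(83)
  for (k in 1:20) {
    ng <- sample(1:4, 1); np <- sample(1:4, 1)
    gts <- lapply(seq_len(ng), function(i)
      disk_mask(40, sample(8:32, 1), sample(8:32, 1), sample(4:8, 1)))
    preds <- lapply(seq_len(np), function(i)
      mask_shift(gts[[sample(ng, 1)]], sample(-4:4, 1), sample(-4:4, 1)))
    scores <- runif(np)
    for (tau in c(0.5, 0.75)) {
      got <- mask_ap(preds, scores, gts, iou_thresholds = tau)
      expect_equal(unname(got$ap), ap_oracle(preds, scores, gts, tau))
    }
  }
})
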