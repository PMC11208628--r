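#' Random geometric transform of an occluder mask
#'
#' Applies an optional horizontal flip, a nearest-neighbour rescale about
#' the mask centroid and an integer translation — the randomisation used
#' when one instance's visible mask is re-used as a synthetic occluder.
#'
#' @param mask binary mask.
#' @param flip mirror horizontally first.
#' @param scale isotropic scale factor.
#' @param dy,dx translation in pixels.
#' @return transformed binary mask on the same raster.
#' @export
mask_transform <- function(mask, flip = FALSE, scale = 1, dy = 0L,
                           dx = 0L) {
  m <- as_mask(mask)
  if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (scale != 1 && sum(m) > 0) {
    idx <- which(m == 1L, arr.ind = TRUE)
    cen <- colMeans(idx)
    h <- nrow(m); w <- ncol(m)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    sr <- round(cen[1] + (yy - cen[1]) / scale)
    sc <- round(cen[2] + (xx - cen[2]) / scale)
    ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
    out <- matrix(0L, h, w)
    out[ok] <- m[cbind(sr[ok], sc[ok])]
    m <- out
  }
  mask_shift(m, as.integer(dy), as.integer(dx))
}

# integer shift that brings the mask centroid to the raster centre;
# canonicalizing the target instance makes the completion task
# translation-free for the network
.center_shift <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  cen <- colMeans(idx)
  c(round(nrow(mask) / 2 - cen[1]), round(ncol(mask) / 2 - cen[2]))
}

.shift_image <- function(image, dy, dx) {
  out <- array(0, dim(image))
  for (ch in seq_len(dim(image)[3])) {
    out[, , ch] <- mask_shift_num(image[, , ch], dy, dx)
  }
  out
}

#' Build the network input stack
#'
#' Concatenates the (possibly erased) RGB image scaled to `[0, 1]`, the
#' input modal-mask channel and the occlusion-boundary channel into the
#' `H x W x 5` array consumed by the network.
#'
#' @param image `H x W x 3` array, 0..255.
#' @param modal binary modal-mask channel.
#' @param boundary binary occlusion-boundary channel.
#' @return `H x W x 5` numeric array.
#' @export
completion_input <- function(image, modal, boundary) {
  H <- dim(image)[1]; W <- dim(image)[2]
  arr <- array(0, c(H, W, 5))
  arr[, , 1:3] <- image / 255
  arr[, , 4] <- modal
  arr[, , 5] <- boundary
  arr
}

#' Draw one training example of the partial-completion game
#'
#' Picks an instance A with a non-empty modal mask and an occluder mask B
#' (another instance's modal mask under a random flip / rescale /
#' translation). In the *occluded* case B is placed over A, the image
#' pixels under B are zeroed, and the network input is `M_A AND NOT B`
#' with target `M_A` — the network must restore what was erased. In the
#' *regularization* case B is placed behind A (its mask minus A becomes
#' the eraser), so nothing of A is deleted: the input modal equals the
#' target and the network must learn to leave an instance alone even
#' though an erased region abuts it. Both cases carry the occluder
#' boundary as the fifth input channel. Training therefore needs only
#' modal masks; no amodal labels are consumed.
#'
#' @param scene_pool list of `scene_record`s with at least two instances
#'   with modal masks between them.
#' @param p_occluded probability of the occluded case (the rest are
#'   regularization cases).
#' @param p_overlap probability that the occluder placement targets
#'   overlap with A in the occluded case.
#' @param min_visible minimum fraction of A's modal pixels that must
#'   survive erasure.
#' @param min_target_pixels instances with fewer modal pixels than this
#'   are not used as completion targets (they remain available as
#'   occluder sources); near-empty fragments make degenerate targets.
#' @return a list of class `completion_sample` with fields
#'   `erased_image`, `input_modal`, `boundary`, `eraser`, `target`,
#'   `case`, `scene_id`, `instance_id`.
#' @export
sample_completion_pair <- function(scene_pool, p_occluded = 0.5,
                                   p_overlap = 0.95, min_visible = 0.3,
                                   min_target_pixels = 40L) {
  cand <- list(); sizes <- numeric(0)
  for (si in seq_along(scene_pool)) {
    for (ii in seq_along(scene_pool[[si]]$instances)) {
      np <- sum(scene_pool[[si]]$instances[[ii]]$modal)
      if (np > 0) {
        cand[[length(cand) + 1L]] <- c(si, ii)
        sizes <- c(sizes, np)
      }
    }
  }
  if (length(cand) < 2) {
    stop("scene pool must contain at least two instances with modal masks")
  }
  targets <- which(sizes >= min_target_pixels)
  if (length(targets) == 0) targets <- seq_along(cand)
  a <- cand[[targets[sample.int(length(targets), 1)]]]
  repeat {
    b <- cand[[sample.int(length(cand), 1)]]
    if (!(b[1] == a[1] && b[2] == a[2])) break
  }
  sc_a <- scene_pool[[a[1]]]
  A <- sc_a$instances[[a[2]]]$modal
  B0 <- scene_pool[[b[1]]]$instances[[b[2]]]$modal
  H <- nrow(A); W <- ncol(A)
  case <- if (stats::runif(1) < p_occluded) "occluded" else
    "regularization"
  # aim points on A's contour: occluders overlap from one side, the way
  # real instances overlap
  apix <- which(extract_boundary(A) == 1L, arr.ind = TRUE)
  if (nrow(apix) == 0) apix <- which(A == 1L, arr.ind = TRUE)
  bcen <- colMeans(which(B0 == 1L, arr.ind = TRUE))
  eraser <- NULL
  for (try in 1:25) {
    flip <- stats::runif(1) < 0.5
    scale <- stats::runif(1, 0.8, 1.2)
    if (stats::runif(1) < p_overlap) {
      # aim the occluder at A so the pair genuinely interacts
      tgt <- apix[sample.int(nrow(apix), 1), ]
      jit <- round(stats::runif(2, -3, 3))
      dy <- round(tgt[1] - bcen[1]) + jit[1]
      dx <- round(tgt[2] - bcen[2]) + jit[2]
    } else {
      dy <- sample.int(H, 1) - round(bcen[1])
      dx <- sample.int(W, 1) - round(bcen[2])
    }
    Bt <- mask_transform(B0, flip, scale, dy, dx)
    if (case == "occluded") {
      # B in front of A: B's mask erases part of A
      visible <- sum(A * (1L - Bt))
      if (sum(Bt * A) > 0 && visible >= min_visible * sum(A)) {
        eraser <- Bt; break
      }
    } else {
      # B behind A: only B's visible remainder is erased, so the erased
      # region abuts A without deleting any of its pixels
      er <- as_mask(Bt * (1L - A))
      if (sum(er) > 0) { eraser <- er; break }
    }
  }
  if (is.null(eraser)) {
    # fall back to a regularization sample with an empty eraser
    case <- "regularization"
    eraser <- matrix(0L, H, W)
  }
  input_modal <- if (case == "occluded") as_mask(A * (1L - eraser)) else A
  img <- sc_a$image
  for (ch in 1:3) img[, , ch][eraser == 1L] <- 0
  structure(list(erased_image = img, input_modal = input_modal,
                 boundary = extract_boundary(eraser), eraser = eraser,
                 target = A, case = case, scene_id = a[1],
                 instance_id = a[2]),
            class = "completion_sample")
}

#' Complete the amodal mask of one instance
#'
#' Runs a trained network on an instance's modal mask. When occluder
#' context (the modal masks of potential occluders) is supplied, the
#' image pixels under the context are zeroed and the context boundary is
#' passed as the occlusion-boundary channel, matching the training
#' distribution of the partial-completion game. The predicted
#' probability map is binarized at `threshold` and OR-ed with the input
#' modal mask, so a completion can never delete visible pixels.
#'
#' @param net trained `amodal_net`.
#' @param image `H x W x 3` scene image, 0..255.
#' @param modal non-empty binary modal mask of the instance.
#' @param occluder_context optional list of binary masks (or one mask) of
#'   potential occluders.
#' @param threshold binarization threshold for the amodal probability
#'   (default 0.2).
#' @param flip_average average the prediction with a horizontally
#'   flipped pass (deterministic test-time symmetrisation).
#' @param clean apply the shape prior to the binarized mask: fill holes
#'   and drop connected components that do not touch the visible mask
#'   (an amodal fruit mask is one solid region around its visible part).
#' @return list with `m` (probability map), `u` (uncertainty map) and
#'   `amodal` (binarized amodal mask, a superset of `modal`).
#' @param contexts list of occluder masks; the instance is completed
#'   once per context (one occluder at a time, the regime the network
#'   was trained in) and the completions are OR-ed. An empty list falls
#'   back to a single completion with no context.
#' @export
complete_amodal <- function(net, image, modal, occluder_context = NULL,
                            threshold = 0.2, flip_average = TRUE,
                            clean = TRUE) {
  modal <- as_mask(modal)
  if (sum(modal) == 0) stop("modal mask is empty")
  H <- nrow(modal); W <- ncol(modal)
  ctx <- matrix(0L, H, W)
  if (!is.null(occluder_context)) {
    if (is.matrix(occluder_context)) {
      occluder_context <- list(occluder_context)
    }
    for (m in occluder_context) ctx <- pmax(ctx, as_mask(m))
  }
  ctx <- as_mask(ctx * (1L - modal))
  img <- image
  for (ch in 1:3) img[, , ch][ctx == 1L] <- 0
  pred <- .predict_centered(net, img, modal, ctx)
  if (flip_average) {
    fl <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]
    imgf <- img
    for (ch in 1:3) imgf[, , ch] <- fl(imgf[, , ch])
    predf <- .predict_centered(net, imgf, fl(modal), fl(ctx))
    pred$m <- (pred$m + fl(predf$m)) / 2
    pred$u <- (pred$u + fl(predf$u)) / 2
  }
  amodal <- as_mask(matrix(as.integer(pred$m >= threshold |
                                        modal == 1L), H, W))
  if (clean) amodal <- .clean_amodal(amodal, modal)
  list(m = pred$m, u = pred$u, amodal = amodal)
}

# centre the instance (the canonical frame the network is trained in),
# predict, then shift the maps back
.predict_centered <- function(net, img, modal, ctx) {
  sh <- .center_shift(modal)
  input <- completion_input(.shift_image(img, sh[1], sh[2]),
                            mask_shift(modal, sh[1], sh[2]),
                            extract_boundary(mask_shift(ctx, sh[1],
                                                        sh[2])))
  pred <- net_predict(net, input)
  list(m = mask_shift_num(pred$m, -sh[1], -sh[2]),
       u = mask_shift_num(pred$u, -sh[1], -sh[2]))
}

# shape prior for a completed fruit mask: one solid region around the
# visible pixels
.clean_amodal <- function(amodal, modal) {
  lab <- EBImage::bwlabel(amodal)
  keep <- unique(lab[modal == 1L & lab > 0])
  m <- matrix(as.integer(lab %in% keep), nrow(amodal))
  m <- matrix(as.integer(EBImage::fillHull(m) > 0), nrow(amodal))
  as_mask(pmax(m, modal))
}

#' @rdname complete_amodal
#' @export
complete_amodal_pairwise <- function(net, image, modal, contexts,
                                     threshold = 0.2) {
  if (length(contexts) == 0) {
    return(complete_amodal(net, image, modal, NULL, threshold))
  }
  H <- nrow(modal); W <- ncol(modal)
  amodal <- as_mask(modal)
  msum <- matrix(0, H, W); usum <- matrix(0, H, W)
  per_context <- vector("list", length(contexts))
  for (k in seq_along(contexts)) {
    cmp <- complete_amodal(net, image, modal, contexts[[k]], threshold)
    per_context[[k]] <- cmp$amodal
    amodal <- as_mask(pmax(amodal, cmp$amodal))
    msum <- pmax(msum, cmp$m)
    usum <- pmax(usum, cmp$u)
  }
  list(m = msum, u = usum, amodal = amodal, per_context = per_context)
}
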