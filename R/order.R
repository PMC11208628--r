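#' Pixel increment of a completion
#'
#' The completion network's evidence that an instance is occluded: the
#' number of pixels the completed amodal mask adds to the visible mask,
#' `|amodal| - |modal|`. The completion pipeline guarantees the amodal
#' prediction is a superset of the modal mask.
#'
#' @param amodal_pred binary completed amodal mask (superset of `modal`).
#' @param modal binary modal mask.
#' @return non-negative integer count.
#' @export
pixel_increment <- function(amodal_pred, modal) {
  if (any(modal == 1L & amodal_pred == 0L)) {
    stop("amodal prediction must contain the modal mask")
  }
  sum(amodal_pred) - sum(modal)
}

#' Pairwise occlusion order from two completion increments
#'
#' Both increments zero means the pair shares a layer (no occlusion),
#' giving 0. A strictly smaller increment for `i` means `i` occludes `j`
#' (value 1); strictly larger means the reverse (value -1). Equal
#' non-zero increments are resolved to 0 (same layer), which keeps the
#' relation antisymmetric under argument swap.
#'
#' @param inc_i,inc_j non-negative completion increments of the two
#'   instances.
#' @return -1, 0 or 1.
#' @export
pairwise_order <- function(inc_i, inc_j) {
  stopifnot(inc_i >= 0, inc_j >= 0)
  if (inc_i == inc_j) return(0L)
  if (inc_i < inc_j) 1L else -1L
}

# adjacency: modal masks whose 3-pixel dilations intersect, or amodal
# estimates that overlap outright
.adjacent_pairs <- function(modals, amodals = NULL) {
  n <- length(modals)
  dil <- lapply(modals, function(m) mask_dilate(m, iterations = 3))
  pairs <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    touch <- sum(dil[[i]] * dil[[j]]) > 0
    if (!touch && !is.null(amodals)) {
      touch <- sum(amodals[[i]] * amodals[[j]]) > 0
    }
    if (touch) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  pairs
}

# pair-restricted increments: within the overlap of the two amodal
# estimates, excluding every other instance's amodal estimate, count the
# hidden (non-modal) pixels of each — so recovered pixels are attributed
# to this pair even in stacks of several mutually occluding instances
.pair_increments <- function(i, j, modals, amodals) {
  ov <- amodals[[i]] * amodals[[j]]
  if (sum(ov) == 0) return(c(0, 0))
  excl <- ov
  for (k in seq_along(amodals)) {
    if (k != i && k != j) excl <- excl * (1L - amodals[[k]])
  }
  c(sum(excl * (1L - modals[[i]])), sum(excl * (1L - modals[[j]])))
}

#' Infer the pairwise occlusion-order graph of a scene
#'
#' Completes every instance with the trained network (occluder context =
#' the other adjacent instances' modal masks, binarization threshold
#' 0.2), then applies the increment rule of [pairwise_order()] to each
#' adjacent pair; non-adjacent pairs get 0. Each unordered pair is
#' evaluated once, so the resulting matrix is antisymmetric by
#' construction. Supplying `amodal_masks` (e.g. ground truth) instead of
#' a network skips the completion step — with exact amodal masks the
#' graph reproduces the generating stacking order.
#'
#' @param scene a `scene_record` with modal masks.
#' @param net trained `amodal_net`, or `NULL` when `amodal_masks` is
#'   given.
#' @param amodal_masks optional list of amodal masks standing in for the
#'   network completions.
#' @param threshold binarization threshold for completions.
#' @param increments `"pair"` (default) restricts each increment to the
#'   pair's exclusive overlap region; `"global"` uses the whole-instance
#'   increment `|amodal| - |modal|`.
#' @param sorting_threshold model-path increments smaller than this
#'   fraction of the smaller modal area of the pair are treated as zero
#'   (the sorting threshold, default 0.2): the same-layer branch of the
#'   increment rule demands exact zeros, which soft network predictions
#'   never produce. Ground-truth masks are exact, so the threshold is
#'   not applied to them.
#' @return list of class `occlusion_graph` with the `N x N` matrix `T`
#'   and `instance_ids`.
#' @export
build_order_graph <- function(scene, net = NULL, amodal_masks = NULL,
                              threshold = 0.2,
                              increments = c("pair", "global"),
                              sorting_threshold = 0.2) {
  increments <- match.arg(increments)
  n <- length(scene$instances)
  ids <- vapply(scene$instances, function(x) x$instance_id, integer(1))
  Tm <- matrix(0L, n, n)
  if (n == 0) {
    return(structure(list(T = Tm, instance_ids = ids),
                     class = "occlusion_graph"))
  }
  modals <- lapply(scene$instances, function(x) x$modal)
  if (is.null(amodal_masks)) {
    if (is.null(net)) stop("supply either a network or amodal masks")
    # model path: complete each member of an adjacent pair with the
    # other's modal mask as the occluder context, so the increment
    # attributes recovered pixels to that pair
    pairs <- .adjacent_pairs(modals)
    for (p in pairs) {
      i <- p[1]; j <- p[2]
      ci <- complete_amodal(net, scene$image, modals[[i]],
                            occluder_context = modals[[j]],
                            threshold = threshold)$amodal
      cj <- complete_amodal(net, scene$image, modals[[j]],
                            occluder_context = modals[[i]],
                            threshold = threshold)$amodal
      inc <- if (increments == "pair") {
        # count only pixels recovered inside the partner's region
        c(sum((ci - modals[[i]]) * mask_dilate(modals[[j]], 2)),
          sum((cj - modals[[j]]) * mask_dilate(modals[[i]], 2)))
      } else {
        c(pixel_increment(ci, modals[[i]]),
          pixel_increment(cj, modals[[j]]))
      }
      inc[inc < sorting_threshold * min(sum(modals[[i]]),
                                        sum(modals[[j]]))] <- 0
      if (inc[1] == 0 && inc[2] == 0) next
      Tm[i, j] <- pairwise_order(inc[1], inc[2])
      Tm[j, i] <- -Tm[i, j]
    }
    return(structure(list(T = Tm, instance_ids = ids),
                     class = "occlusion_graph"))
  }
  pairs <- .adjacent_pairs(modals, amodal_masks)
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    inc <- if (increments == "pair") {
      .pair_increments(i, j, modals, amodal_masks)
    } else {
      c(pixel_increment(pmax(amodal_masks[[i]], modals[[i]]),
                        modals[[i]]),
        pixel_increment(pmax(amodal_masks[[j]], modals[[j]]),
                        modals[[j]]))
    }
    if (inc[1] == 0 && inc[2] == 0) next
    Tm[i, j] <- pairwise_order(inc[1], inc[2])
    Tm[j, i] <- -Tm[i, j]
  }
  structure(list(T = Tm, instance_ids = ids), class = "occlusion_graph")
}

#' Heuristic occlusion-order baselines
#'
#' `area`: larger instances are sorted as foreground, so for an adjacent
#' pair the larger-area modal mask is taken to occlude the smaller.
#' `yaxis`: instances whose bounding boxes reach closer to the bottom of
#' the image are placed in front. Ties give 0.
#'
#' @param scene a `scene_record` with modal masks.
#' @param mode `"area"` or `"yaxis"`.
#' @return an `occlusion_graph`.
#' @export
baseline_order <- function(scene, mode = c("area", "yaxis")) {
  mode <- match.arg(mode)
  n <- length(scene$instances)
  ids <- vapply(scene$instances, function(x) x$instance_id, integer(1))
  Tm <- matrix(0L, n, n)
  if (n > 0) {
    modals <- lapply(scene$instances, function(x) x$modal)
    key <- switch(mode,
      area = vapply(modals, sum, numeric(1)),
      yaxis = vapply(scene$instances, function(x)
        x$bbox["y"] + x$bbox["h"], numeric(1)))
    for (p in .adjacent_pairs(modals)) {
      i <- p[1]; j <- p[2]
      if (key[i] == key[j]) next
      Tm[i, j] <- if (key[i] > key[j]) 1L else -1L
      Tm[j, i] <- -Tm[i, j]
    }
  }
  structure(list(T = Tm, instance_ids = ids), class = "occlusion_graph")
}
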