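#' Split image ids into train / validation / test sets
#'
#' First draws `n_test` test ids by a seeded shuffle of all ids, then
#' divides the remainder into train and validation by the given ratio,
#' with the larger share going to the training set. When the ratio is not
#' achievable in integers the train share is floored and the remainder
#' goes to validation (a note is emitted). The canonical bookkeeping for
#' an occlusion dataset of 1000 images with a 100-image test set and a
#' 9:1 train/validation ratio yields 810 / 90 / 100.
#'
#' @param n_total total number of images.
#' @param n_test number of test images (`< n_total`).
#' @param train_val_ratio length-2 positive numeric, e.g. `c(9, 1)`.
#' @param seed integer seed for the shuffle.
#' @return list with disjoint integer vectors `train_ids`, `val_ids`,
#'   `test_ids` whose union is `1:n_total`.
#' @export
split_dataset <- function(n_total, n_test, train_val_ratio = c(9, 1),
                          seed = 1L) {
  stopifnot(n_test < n_total, length(train_val_ratio) == 2,
            all(train_val_ratio > 0))
  ids <- with_seed(seed, sample.int(n_total))
  test_ids <- sort(ids[seq_len(n_test)])
  rest <- ids[setdiff(seq_len(n_total), seq_len(n_test))]
  n_rest <- length(rest)
  r <- sort(train_val_ratio, decreasing = TRUE)  # larger share to train
  exact <- n_rest * r[1] / sum(r)
  n_train <- floor(exact)
  if (n_train != exact) {
    message(sprintf(
      "train/val ratio %g:%g not achievable in integers for %d items; %s",
      r[1], r[2], n_rest,
      sprintf("train floored to %d, %d to validation",
              n_train, n_rest - n_train)))
  }
  list(train_ids = sort(rest[seq_len(n_train)]),
       val_ids = sort(rest[setdiff(seq_len(n_rest), seq_len(n_train))]),
       test_ids = test_ids)
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Geometric scene transforms
#'
#' Each transform is applied consistently to the image and every mask of
#' the scene. `scene_flip()` mirrors horizontally (an involution);
#' `scene_translate()` pans by whole pixels with zero padding;
#' `scene_crop()` extracts a window (instances whose modal mask becomes
#' empty are dropped, the scene itself is kept). The ground-truth order
#' matrix is carried along (rows/columns of dropped instances removed).
#'
#' @param scene a `scene_record`.
#' @return a transformed `scene_record`.
#' @export
scene_flip <- function(scene) {
  flip_m <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  img <- scene$image
  for (ch in 1:3) img[, , ch] <- flip_m(img[, , ch])
  insts <- lapply(scene$instances, function(inst) {
    instance_record(inst$instance_id, flip_m(inst$modal),
                    if (!is.null(inst$amodal)) flip_m(inst$amodal),
                    inst$category, inst$extra)
  })
  scene_record(img, insts, scene$order_matrix, scene$extra)
}

#' @rdname scene_flip
#' @param dy,dx translation in pixels (positive: down/right).
#' @export
scene_translate <- function(scene, dy, dx) {
  shift_img <- function(img) {
    out <- array(0, dim(img))
    for (ch in 1:3) out[, , ch] <- mask_shift_num(img[, , ch], dy, dx)
    out
  }
  insts <- lapply(scene$instances, function(inst) {
    instance_record(inst$instance_id, mask_shift(inst$modal, dy, dx),
                    if (!is.null(inst$amodal))
                      mask_shift(inst$amodal, dy, dx),
                    inst$category, inst$extra)
  })
  scene_record(shift_img(scene$image), insts, scene$order_matrix,
               scene$extra)
}

# numeric variant of mask_shift for image channels
mask_shift_num <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  sr0 <- max(1, 1 - dy); sr1 <- min(h, h - dy)
  sc0 <- max(1, 1 - dx); sc1 <- min(w, w - dx)
  if (sr0 > sr1 || sc0 > sc1) return(out)
  sr <- sr0:sr1; sc <- sc0:sc1
  out[sr + dy, sc + dx] <- m[sr, sc]
  out
}

#' @rdname scene_flip
#' @param y0,x0 0-based top-left corner of the crop window.
#' @param h,w crop window size in pixels (must fit inside the image).
#' @export
scene_crop <- function(scene, y0, x0, h, w) {
  H <- dim(scene$image)[1]; W <- dim(scene$image)[2]
  if (h > H || w > W || y0 < 0 || x0 < 0 || y0 + h > H || x0 + w > W) {
    stop("crop window larger than image or out of bounds")
  }
  rows <- (y0 + 1):(y0 + h); cols <- (x0 + 1):(x0 + w)
  img <- scene$image[rows, cols, , drop = FALSE]
  keep <- logical(length(scene$instances))
  insts <- list()
  for (i in seq_along(scene$instances)) {
    inst <- scene$instances[[i]]
    modal <- inst$modal[rows, cols, drop = FALSE]
    if (sum(modal) == 0) next
    keep[i] <- TRUE
    insts[[length(insts) + 1L]] <-
      instance_record(inst$instance_id, modal,
                      if (!is.null(inst$amodal))
                        inst$amodal[rows, cols, drop = FALSE],
                      inst$category, inst$extra)
  }
  om <- scene$order_matrix
  if (!is.null(om)) om <- om[keep, keep, drop = FALSE]
  scene_record(img, insts, om, scene$extra)
}

#' Augment a training set of scenes
#'
#' Produces `multiplier` augmented copies of every scene, each applying
#' one seeded transform drawn from the enabled set (horizontal flip,
#' translation of up to `translate_frac` of each dimension, or a random
#' crop of `crop_frac` of each dimension). With an empty transform set the
#' copies are identities. Tripling an 810-scene training split yields
#' 2430 scenes.
#'
#' @param train_scenes list of `scene_record`s carrying modal masks.
#' @param multiplier integer >= 1; output count is `multiplier` times the
#'   input count.
#' @param seed integer seed.
#' @param transforms subset of `c("flip", "translate", "crop")`.
#' @param translate_frac maximum pan as a fraction of each dimension.
#' @param crop_frac crop window size as a fraction of each dimension.
#' @return list of augmented `scene_record`s.
#' @export
augment_training_set <- function(train_scenes, multiplier, seed = 1L,
                                 transforms = c("flip", "translate", "crop"),
                                 translate_frac = 0.1, crop_frac = 0.8) {
  stopifnot(multiplier >= 1)
  with_seed(seed, {
    out <- vector("list", length(train_scenes) * multiplier)
    k <- 0L
    for (sc in train_scenes) {
      H <- dim(sc$image)[1]; W <- dim(sc$image)[2]
      for (m in seq_len(multiplier)) {
        k <- k + 1L
        if (length(transforms) == 0) { out[[k]] <- sc; next }
        tr <- sample(transforms, 1)
        out[[k]] <- switch(tr,
          flip = scene_flip(sc),
          translate = {
            dy <- sample.int(2 * floor(H * translate_frac) + 1, 1) -
              floor(H * translate_frac) - 1
            dx <- sample.int(2 * floor(W * translate_frac) + 1, 1) -
              floor(W * translate_frac) - 1
            scene_translate(sc, dy, dx)
          },
          crop = {
            ch <- max(1, round(H * crop_frac))
            cw <- max(1, round(W * crop_frac))
            y0 <- sample.int(H - ch + 1, 1) - 1
            x0 <- sample.int(W - cw + 1, 1) - 1
            scene_crop(sc, y0, x0, ch, cw)
          })
      }
    }
    out
  })
}
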