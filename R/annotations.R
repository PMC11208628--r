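#' Instance and scene records
#'
#' An `instance_record` holds one object: its modal (visible) mask, an
#' optional amodal (full-shape) mask, a category label and the tight
#' bounding box of the modal mask. A `scene_record` holds an 8-bit RGB
#' image (an `H x W x 3` array with values 0..255), an ordered list of
#' instances sharing the image raster, and an optional `N x N` ground-truth
#' occlusion-order matrix with entries in \{-1, 0, 1\}: `T[i, j] = 1` means
#' instance `i` lies above (occludes) instance `j` and their full shapes
#' overlap, `-1` the reverse, `0` no occlusion between the pair.
#'
#' @param instance_id integer id, unique within a scene.
#' @param modal binary modal mask.
#' @param amodal optional binary amodal mask; when present the modal mask
#'   must be a pixelwise subset of it.
#' @param category category label.
#' @param extra list of unknown annotation fields preserved opaquely.
#' @return a list of class `instance_record`.
#' @export
instance_record <- function(instance_id, modal, amodal = NULL,
                            category = "fruit", extra = list()) {
  modal <- as_mask(modal)
  if (!is.null(amodal)) {
    amodal <- as_mask(amodal)
    if (!all(dim(amodal) == dim(modal))) {
      stop("modal and amodal masks must share the same raster")
    }
    if (any(modal == 1L & amodal == 0L)) {
      warning(sprintf(
        "instance %s: modal mask is not a subset of the amodal mask",
        format(instance_id)))
    }
  }
  structure(list(instance_id = as.integer(instance_id),
                 category = as.character(category),
                 modal = modal, amodal = amodal,
                 bbox = mask_bbox(modal), extra = extra),
            class = "instance_record")
}

#' @rdname instance_record
#' @param image `H x W x 3` array with values in 0..255.
#' @param instances list of `instance_record`s.
#' @param order_matrix optional `N x N` matrix in \{-1, 0, 1\}.
#' @export
scene_record <- function(image, instances, order_matrix = NULL,
                         extra = list()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  for (inst in instances) {
    if (!all(dim(inst$modal) == c(h, w))) {
      stop("all masks must share the image's height and width")
    }
  }
  n <- length(instances)
  if (!is.null(order_matrix)) {
    order_matrix <- matrix(as.integer(order_matrix), n, n)
    if (any(diag(order_matrix) != 0L) ||
        any(order_matrix != -t(order_matrix))) {
      stop("order_matrix must have zero diagonal and be antisymmetric")
    }
  }
  structure(list(image = image, instances = instances,
                 order_matrix = order_matrix, extra = extra),
            class = "scene_record")
}

#' @export
print.scene_record <- function(x, ...) {
  cat(sprintf("scene_record: %dx%d image, %d instance(s)%s\n",
              dim(x$image)[1], dim(x$image)[2], length(x$instances),
              if (is.null(x$order_matrix)) "" else ", with order matrix"))
  invisible(x)
}

.inst_to_annotation <- function(inst, image_id, ann_id) {
  ann <- list(id = ann_id, image_id = image_id, category = inst$category,
              bbox = unname(inst$bbox),
              visible_mask = rle_encode(inst$modal))
  if (!is.null(inst$amodal)) ann$amodal_mask <- rle_encode(inst$amodal)
  c(ann, inst$extra)
}

#' Write a dataset of scenes to disk
#'
#' Writes one PNG per scene under `images/` and a single COCO-style
#' `annotations.json` carrying, per annotation, a `visible_mask` and an
#' optional `amodal_mask` as uncompressed column-major RLE, and per image
#' an optional `order_matrix`. Unknown fields found by [read_dataset()] are
#' written back unchanged.
#'
#' @param scenes list of `scene_record`s.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(scenes, path) {
  dir.create(file.path(path, "images"), recursive = TRUE,
             showWarnings = FALSE)
  images <- list(); annotations <- list(); ann_id <- 0L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    fn <- sprintf("scene_%04d.png", i)
    png::writePNG(sc$image / 255, file.path(path, "images", fn))
    img <- list(id = i, file_name = fn,
                height = dim(sc$image)[1], width = dim(sc$image)[2])
    if (!is.null(sc$order_matrix)) {
      img$order_matrix <- lapply(seq_len(nrow(sc$order_matrix)),
                                 function(r) as.integer(sc$order_matrix[r, ]))
    }
    img <- c(img, sc$extra)
    images[[length(images) + 1L]] <- img
    for (inst in sc$instances) {
      ann_id <- ann_id + 1L
      annotations[[length(annotations) + 1L]] <-
        .inst_to_annotation(inst, i, ann_id)
    }
  }
  obj <- list(images = images, annotations = annotations)
  jsonlite::write_json(obj, file.path(path, "annotations.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.known_ann_fields <- c("id", "image_id", "category", "bbox",
                       "visible_mask", "amodal_mask")
.known_img_fields <- c("id", "file_name", "height", "width", "order_matrix")

#' Read a dataset of scenes from disk
#'
#' @param path directory written by [write_dataset()] (or following the
#'   same dialect).
#' @return list of `scene_record`s.
#' @export
read_dataset <- function(path) {
  obj <- jsonlite::read_json(file.path(path, "annotations.json"))
  img_ids <- vapply(obj$images, function(im) as.integer(im$id), integer(1))
  by_image <- split(obj$annotations,
                    vapply(obj$annotations, function(a)
                      as.integer(a$image_id), integer(1)))
  bad <- setdiff(as.integer(names(by_image)), img_ids)
  if (length(bad) > 0) {
    stop(sprintf("annotation(s) reference missing image id(s): %s",
                 paste(bad, collapse = ", ")))
  }
  scenes <- vector("list", length(obj$images))
  for (k in seq_along(obj$images)) {
    im <- obj$images[[k]]
    arr <- png::readPNG(file.path(path, "images", im$file_name))
    if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
    if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
    image <- round(arr * 255)
    anns <- by_image[[as.character(im$id)]]
    insts <- list()
    for (a in anns) {
      vm <- rle_decode(list(size = unlist(a$visible_mask$size),
                            counts = unlist(a$visible_mask$counts)),
                       annotation_id = a$id)
      am <- NULL
      if (!is.null(a$amodal_mask)) {
        am <- rle_decode(list(size = unlist(a$amodal_mask$size),
                              counts = unlist(a$amodal_mask$counts)),
                         annotation_id = a$id)
      }
      extra <- a[setdiff(names(a), .known_ann_fields)]
      insts[[length(insts) + 1L]] <-
        instance_record(a$id, vm, am, category = a$category %||% "fruit",
                        extra = extra)
    }
    om <- NULL
    if (!is.null(im$order_matrix)) {
      om <- do.call(rbind, lapply(im$order_matrix, function(r)
        as.integer(unlist(r))))
    }
    scenes[[k]] <- scene_record(image, insts, order_matrix = om,
                                extra = im[setdiff(names(im),
                                                   .known_img_fields)])
  }
  scenes
}

`%||%` <- function(a, b) if (is.null(a)) b else a
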