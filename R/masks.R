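#' Binary masks
#'
#' A binary mask is an ordinary integer matrix with values in \{0, 1\};
#' rows index image rows (top to bottom), columns index image columns
#' (left to right). All modal/amodal reasoning in the package operates on
#' these rasters. Coordinates are 0-based (row, col) with a top-left
#' origin; bounding boxes `(x, y, w, h)` are half-open,
#' `[x, x + w) x [y, y + h)`, with `x` the 0-based column of the left edge.
#'
#' @param m a matrix (numeric or integer) of zeros and ones.
#' @return `as_mask()` returns an integer matrix of 0/1.
#' @export
as_mask <- function(m) {
  if (!is.matrix(m)) stop("mask must be a matrix")
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m != 0L & m != 1L)) {
    stop("mask values must all be 0 or 1")
  }
  m
}

#' @rdname as_mask
#' @export
is_valid_mask <- function(m) {
  is.matrix(m) && nrow(m) >= 1 && ncol(m) >= 1 &&
    !any(is.na(m)) && all(m == 0 | m == 1)
}

#' Tight bounding box of a mask
#'
#' @param mask binary mask matrix.
#' @return `c(x, y, w, h)` in pixels, 0-based half-open; all zeros for an
#'   empty mask.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(x = 0, y = 0, w = 0, h = 0))
  r <- range(idx[, 1]); c <- range(idx[, 2])
  c(x = c[1] - 1, y = r[1] - 1, w = c[2] - c[1] + 1, h = r[2] - r[1] + 1)
}

#' Encode a mask as uncompressed run-length counts
#'
#' Uses the COCO uncompressed-counts convention: the mask is flattened in
#' column-major order and encoded as alternating run lengths, starting
#' with the count of zeros (which may be 0 when the first pixel is
#' foreground).
#'
#' @param mask binary mask matrix.
#' @return a list with `size = c(h, w)` and integer vector `counts`.
#' @export
rle_encode <- function(mask) {
  mask <- as_mask(mask)
  v <- as.integer(mask)            # column-major flatten
  r <- rle(v)
  counts <- r$lengths
  if (length(v) == 0) counts <- integer(0)
  if (length(counts) > 0 && r$values[1] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

#' Decode uncompressed run-length counts to a mask
#'
#' @param rle list with `size` and `counts` as produced by [rle_encode()].
#' @param annotation_id optional id used in error messages when the counts
#'   are malformed.
#' @return binary mask matrix.
#' @export
rle_decode <- function(rle, annotation_id = NULL) {
  h <- as.integer(rle$size[1]); w <- as.integer(rle$size[2])
  counts <- as.integer(rle$counts)
  if (any(is.na(counts)) || any(counts < 0) || sum(counts) != h * w) {
    where <- if (is.null(annotation_id)) "" else
      sprintf(" in annotation id %s", format(annotation_id))
    stop(sprintf(
      "malformed RLE counts%s: counts sum to %d but mask has %d pixels",
      where, sum(counts), h * w))
  }
  vals <- rep(rep_len(c(0L, 1L), length(counts)), counts)
  matrix(vals, nrow = h, ncol = w)
}

# 3x3 cross-structuring-element morphology via EBImage
.cross3 <- function() EBImage::makeBrush(3, shape = "diamond")

#' Morphological helpers
#'
#' `mask_erode()`/`mask_dilate()` apply a 3x3 cross structuring element
#' (optionally iterated); `extract_boundary()` returns the 1-pixel-wide
#' inner contour, `mask AND NOT erode(mask)`.
#'
#' @param mask binary mask matrix.
#' @param iterations number of times the 3x3 cross is applied.
#' @return binary mask matrix of the same shape.
#' @export
mask_erode <- function(mask, iterations = 1) {
  m <- as_mask(mask)
  for (i in seq_len(iterations)) m <- EBImage::erode(m, .cross3())
  as_mask(matrix(as.integer(m), nrow(mask), ncol(mask)))
}

#' @rdname mask_erode
#' @export
mask_dilate <- function(mask, iterations = 1) {
  m <- as_mask(mask)
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, .cross3())
  as_mask(matrix(as.integer(m), nrow(mask), ncol(mask)))
}

#' @rdname mask_erode
#' @export
extract_boundary <- function(mask) {
  m <- as_mask(mask)
  if (sum(m) == 0) return(m)
  as_mask(m * (1L - mask_erode(m)))
}

#' Shift a mask by whole pixels with zero padding
#'
#' @param mask binary mask matrix.
#' @param dy,dx shift in rows/columns (positive moves down/right).
#' @return shifted mask of the same shape.
#' @export
mask_shift <- function(mask, dy, dx) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  sr0 <- max(1, 1 - dy); sr1 <- min(h, h - dy)   # source rows
  sc0 <- max(1, 1 - dx); sc1 <- min(w, w - dx)
  if (sr0 > sr1 || sc0 > sc1) return(out)
  sr <- sr0:sr1; sc <- sc0:sc1
  out[sr + dy, sc + dx] <- mask[sr, sc]
  out
}
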