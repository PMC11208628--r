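#' Mean-value coordinates of a point with respect to a polygon
#'
#' Computes the generalized barycentric weights of an interior point `x`
#' with respect to the ordered vertices of a simple polygon:
#' \deqn{w_i = \frac{\tan(\alpha_{i-1}/2) + \tan(\alpha_i/2)}{\|p_i - x\|},
#'       \qquad \lambda_i = w_i / \sum_j w_j,}
#' where \eqn{\alpha_i} is the signed angle at `x` between the directions
#' to `p_i` and `p_{i+1}`. The weights form a partition of unity and, for
#' convex polygons, are non-negative and reproduce `x` exactly
#' (`sum(lambda * p) == x`, linear precision).
#'
#' @param x numeric length-2 point `(row, col)` strictly inside the
#'   polygon.
#' @param boundary `m x 2` matrix of ordered polygon vertices `(row, col)`
#'   (either orientation); `m >= 3`.
#' @return numeric vector of `m` weights summing to 1.
#' @export
mvc_coordinates <- function(x, boundary) {
  w <- .mvc_weight_matrix(matrix(x, nrow = 1), boundary)
  as.numeric(w)
}

# weights for many points at once: points n x 2, boundary m x 2
# returns n x m matrix of normalized weights
.mvc_weight_matrix <- function(points, boundary) {
  stopifnot(ncol(points) == 2, ncol(boundary) == 2, nrow(boundary) >= 3)
  n <- nrow(points); m <- nrow(boundary)
  dr <- outer(points[, 1], boundary[, 1], "-") * -1  # p_i - x, row comp
  dc <- outer(points[, 2], boundary[, 2], "-") * -1
  d <- sqrt(dr^2 + dc^2)
  if (any(d < 1e-9)) {
    stop("point lies on the polygon boundary; use the boundary value directly")
  }
  nxt <- c(2:m, 1)
  # signed angle between direction i and direction i+1 at each point
  cross <- dr * dc[, nxt] - dc * dr[, nxt]
  dot <- dr * dr[, nxt] + dc * dc[, nxt]
  alpha <- atan2(cross, dot)
  if (any(abs(abs(alpha) - pi) < 1e-9)) {
    stop("point lies on the polygon boundary; use the boundary value directly")
  }
  t_half <- tan(alpha / 2)
  prv <- c(m, 1:(m - 1))
  w <- (t_half[, prv, drop = FALSE] + t_half) / d
  w / rowSums(w)
}

# ordered outer contour of a mask as (row, col) vertices (1-based, sub-pixel
# identical to pixel centers); uses EBImage's contour tracer
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(as_mask(mask))
  if (length(oc) == 0) stop("mask is empty")
  # largest contour; EBImage returns 0-based (dim1, dim2) coordinates
  sizes <- vapply(oc, nrow, integer(1))
  v <- oc[[which.max(sizes)]] + 1
  colnames(v) <- c("row", "col")
  v
}

#' Seamlessly clone an image patch using a mean-value membrane
#'
#' Transfers the region of `source` delimited by the polygon `boundary`
#' into `target` at `offset`, correcting the interior with a smooth
#' membrane interpolating the source/target mismatch along the boundary:
#' \deqn{r(x) = \sum_i \lambda_i(x)\,(f^*(p_i) - g(p_i)),\qquad
#'       \mathrm{out}(x) = g(x) + r(x)}
#' with `g` the source, `f*` the target along the placed boundary and
#' \eqn{\lambda} the mean-value coordinates of `x`. The membrane
#' interpolates its boundary data, so along the boundary the composite
#' equals the target exactly; it is a smooth (near-harmonic) interpolant
#' inside.
#'
#' @param source `H x W x 3` array, values 0..255.
#' @param boundary ordered polygon vertices `(row, col)` in source
#'   coordinates (e.g. from the contour of the patch mask).
#' @param interior `k x 2` integer matrix of pixels strictly inside the
#'   polygon, in source coordinates; computed from the polygon when `NULL`.
#' @param target `H' x W' x 3` array, values 0..255.
#' @param offset integer `(dy, dx)` added to source coordinates to place
#'   the patch in the target.
#' @param subsample keep every `subsample`-th boundary vertex when
#'   evaluating the membrane (1 = every boundary pixel).
#' @return the composited target image.
#' @export
mvc_clone <- function(source, boundary, target, offset = c(0L, 0L),
                      interior = NULL, subsample = 1L) {
  stopifnot(length(dim(source)) == 3, length(dim(target)) == 3)
  if (is.null(interior)) interior <- polygon_interior(boundary)
  placed <- sweep(boundary, 2, offset, "+")
  ht <- dim(target)[1]; wt <- dim(target)[2]
  if (min(placed) < 1 || max(placed[, 1]) > ht || max(placed[, 2]) > wt) {
    stop("placed polygon exceeds target bounds")
  }
  if (nrow(interior) == 0) return(target)
  bnd <- boundary
  if (subsample > 1L) {
    keep <- seq(1, nrow(boundary), by = subsample)
    bnd <- boundary[keep, , drop = FALSE]
  }
  lam <- .mvc_weight_matrix(interior, bnd)
  placed_bnd <- sweep(bnd, 2, offset, "+")
  placed_int <- sweep(interior, 2, offset, "+")
  out <- target
  bidx_s <- cbind(bnd[, 1], bnd[, 2])
  bidx_t <- cbind(placed_bnd[, 1], placed_bnd[, 2])
  iidx_s <- cbind(interior[, 1], interior[, 2])
  iidx_t <- cbind(placed_int[, 1], placed_int[, 2])
  for (ch in 1:3) {
    g_b <- source[, , ch][bidx_s]
    f_b <- target[, , ch][bidx_t]
    membrane <- as.numeric(lam %*% (f_b - g_b))
    vals <- source[, , ch][iidx_s] + membrane
    out[, , ch][iidx_t] <- pmin(255, pmax(0, vals))
  }
  out
}

#' Integer pixels strictly inside a polygon
#'
#' @param boundary ordered polygon vertices `(row, col)`.
#' @return `k x 2` matrix of interior pixel coordinates.
#' @export
polygon_interior <- function(boundary) {
  r0 <- floor(min(boundary[, 1])); r1 <- ceiling(max(boundary[, 1]))
  c0 <- floor(min(boundary[, 2])); c1 <- ceiling(max(boundary[, 2]))
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  inside <- pracma::inpolygon(grid$row, grid$col,
                              boundary[, 1], boundary[, 2],
                              boundary = FALSE)
  # drop points on (or numerically at) the boundary vertices
  pts <- as.matrix(grid[inside, , drop = FALSE])
  if (nrow(pts) == 0) return(matrix(numeric(0), 0, 2))
  on_bnd <- rep(FALSE, nrow(pts))
  d2 <- outer(pts[, 1], boundary[, 1], "-")^2 +
    outer(pts[, 2], boundary[, 2], "-")^2
  on_bnd <- apply(d2, 1, min) < 1e-12
  pts[!on_bnd, , drop = FALSE]
}

#' Clone a masked patch between images
#'
#' Convenience wrapper around [mvc_clone()]: the patch is described by a
#' binary mask in source coordinates; its outer contour becomes the
#' membrane boundary and the mask interior (mask minus its 1-pixel
#' contour) the cloned region.
#'
#' @param source,target images (`H x W x 3`, 0..255).
#' @param mask binary patch mask in source coordinates.
#' @param offset integer `(dy, dx)` placement shift.
#' @param subsample boundary subsampling stride passed to [mvc_clone()].
#' @return list with the composited `image` and the placed binary `mask`
#'   in target coordinates.
#' @export
mvc_clone_mask <- function(source, mask, target, offset = c(0L, 0L),
                           subsample = 1L) {
  bnd <- mask_contour(mask)
  inner <- as_mask(mask * (1L - extract_boundary(mask)))
  interior <- which(inner == 1L, arr.ind = TRUE)
  colnames(interior) <- c("row", "col")
  img <- mvc_clone(source, bnd, target, offset = offset,
                   interior = interior, subsample = subsample)
  # boundary pixels take the target values exactly (zero membrane there);
  # the placed mask is the full patch mask shifted into target coords
  placed <- matrix(0L, dim(target)[1], dim(target)[2])
  src_idx <- which(as_mask(mask) == 1L, arr.ind = TRUE)
  dst <- cbind(src_idx[, 1] + offset[1], src_idx[, 2] + offset[2])
  keep <- dst[, 1] >= 1 & dst[, 1] <= nrow(placed) &
    dst[, 2] >= 1 & dst[, 2] <= ncol(placed)
  placed[dst[keep, , drop = FALSE]] <- 1L
  list(image = img, mask = placed)
}
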