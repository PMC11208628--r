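#' Specification of a synthetic occluded scene
#'
#' The generator emulates clusters of round fruit seen against foliage:
#' superellipse-shaped instances with radial shading, overlapping in a
#' known stacking order (later-placed instances lie above earlier ones),
#' plus optional elongated leaf-like distractor occluders on top, an
#' illumination gradient and additive Gaussian noise. Because every
#' instance is rasterized before occlusion, the generator knows the exact
#' amodal (full-shape) mask of every instance, the modal mask that
#' survives occlusion, and the true pairwise occlusion-order matrix.
#'
#' @param size image side in pixels (square scenes).
#' @param n_range inclusive range for the number of instances.
#' @param shape one of `"disk"`, `"ellipse"`, `"superellipse"`.
#' @param radius inclusive range of instance radii in pixels.
#' @param overlap target occlusion depth in `[0, 1)`: when a new instance
#'   is anchored to an existing one its centre distance is drawn so the
#'   pair overlaps by roughly this fraction of the smaller radius.
#' @param p_overlap probability that a new instance is anchored to
#'   overlap an existing one (rather than placed freely).
#' @param distractors expected number of leaf-like distractor occluders
#'   (Poisson, capped at 3).
#' @param illum amplitude of the linear illumination gradient (0..255
#'   intensity units).
#' @param noise_sd standard deviation of the additive Gaussian pixel
#'   noise (intensity units).
#' @param seed default seed used by [generate_scene()].
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(size = 64L, n_range = c(2L, 4L),
                       shape = c("superellipse", "disk", "ellipse"),
                       radius = c(9, 16), overlap = 0.35, p_overlap = 0.8,
                       distractors = 1, illum = 20, noise_sd = 4,
                       seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(overlap >= 0, overlap < 1, diff(range(n_range)) >= 0,
            all(radius > 0))
  structure(list(size = as.integer(size), n_range = as.integer(n_range),
                 shape = shape, radius = radius, overlap = overlap,
                 p_overlap = p_overlap, distractors = distractors,
                 illum = illum, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# superellipse raster: returns list(mask, s) where s is the normalized
# radial field (0 centre .. 1 rim) inside the mask, used for shading
superellipse_raster <- function(size, cy, cx, a, b, e, phi) {
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  u <- (xx - cx) * cos(phi) + (yy - cy) * sin(phi)
  v <- -(xx - cx) * sin(phi) + (yy - cy) * cos(phi)
  s <- (abs(u) / a)^e + (abs(v) / b)^e
  mask <- matrix(as.integer(s <= 1), size, size)
  list(mask = mask, s = pmin(1, s^(1 / e)))
}

# wavy elongated blob standing in for a leaf or branch occluder
leaf_raster <- function(size, cy, cx, len, wid, phi, wobble) {
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  u <- (xx - cx) * cos(phi) + (yy - cy) * sin(phi)
  v <- -(xx - cx) * sin(phi) + (yy - cy) * cos(phi)
  halfw <- wid * (1 + wobble * sin(3 * pi * u / len)) *
    pmax(0, 1 - (u / len)^2)
  matrix(as.integer(abs(v) <= halfw & abs(u) <= len), size, size)
}

.sample_instance_geometry <- function(spec) {
  r <- runif(1, spec$radius[1], spec$radius[2])
  switch(spec$shape,
    disk = list(a = r, b = r, e = 2, phi = 0, r = r),
    ellipse = {
      asp <- runif(1, 0.7, 1)
      list(a = r, b = r * asp, e = 2, phi = runif(1, 0, pi), r = r)
    },
    superellipse = {
      asp <- runif(1, 0.8, 1.2)
      list(a = r, b = r * asp, e = runif(1, 1.8, 2.8),
           phi = runif(1, 0, pi), r = r)
    })
}

#' Generate one synthetic occluded scene
#'
#' Instances are placed in stacking order (each later instance lies above
#' all earlier ones); with probability `p_overlap` a new instance is
#' anchored to overlap an existing one at the spec's target depth.
#' Distractor occluders sit above all fruit. The modal mask of instance
#' `i` is its amodal mask minus the union of the amodal masks stacked
#' above it and the distractors; instances left with an empty modal mask
#' are dropped. The ground-truth order matrix has `T[i, j] = 1` iff `i`
#' is above `j` and their amodal masks overlap. Layouts are re-drawn (a
#' bounded number of times) until every overlapping pair retains some
#' pair-exclusive overlap evidence; if the overlap target cannot be met
#' the best-effort scene is returned with the achieved overlap recorded
#' in attribute `achieved_overlap`.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed (defaults to `spec$seed`); the same spec and
#'   seed always produce the identical scene.
#' @return a `scene_record` with modal and amodal masks and order matrix.
#' @export
generate_scene <- function(spec, seed = spec$seed) {
  with_seed(seed, .generate_scene_impl(spec))
}

.generate_scene_impl <- function(spec) {
  for (attempt in 1:10) {
    sc <- .draw_scene_layout(spec)
    if (isTRUE(attr(sc, "valid"))) return(sc)
  }
  sc
}

.draw_scene_layout <- function(spec) {
  size <- spec$size
  n <- if (spec$n_range[1] == spec$n_range[2]) spec$n_range[1] else
    sample(seq(spec$n_range[1], spec$n_range[2]), 1)
  geoms <- list(); centers <- matrix(0, 0, 2)
  amodal <- list()
  for (i in seq_len(n)) {
    g <- .sample_instance_geometry(spec)
    placed <- FALSE
    for (try in 1:20) {
      if (i > 1 && runif(1) < spec$p_overlap) {
        j <- sample.int(i - 1, 1)
        rj <- geoms[[j]]$r
        depth <- spec$overlap * runif(1, 0.7, 1.3)
        d <- (g$r + rj) - 2 * depth * min(g$r, rj)
        th <- runif(1, 0, 2 * pi)
        cy <- centers[j, 1] + d * sin(th)
        cx <- centers[j, 2] + d * cos(th)
      } else {
        m <- g$r * 0.6
        cy <- runif(1, 1 + m, size - m)
        cx <- runif(1, 1 + m, size - m)
      }
      if (cy > 2 && cy < size - 1 && cx > 2 && cx < size - 1) {
        placed <- TRUE; break
      }
    }
    if (!placed) { cy <- size / 2; cx <- size / 2 }
    ras <- superellipse_raster(size, cy, cx, g$a, g$b, g$e, g$phi)
    geoms[[i]] <- c(g, list(cy = cy, cx = cx, s = ras$s))
    centers <- rbind(centers, c(cy, cx))
    amodal[[i]] <- ras$mask
  }
  # distractor occluders above every fruit
  nd <- min(3, stats::rpois(1, spec$distractors))
  dmask <- matrix(0L, size, size)
  dlist <- list()
  for (k in seq_len(nd)) {
    lm <- leaf_raster(size, runif(1, 5, size - 4), runif(1, 5, size - 4),
                      len = runif(1, 0.25, 0.5) * size,
                      wid = runif(1, 2.5, 5), phi = runif(1, 0, pi),
                      wobble = runif(1, 0.2, 0.5))
    dlist[[k]] <- lm
    dmask <- pmax(dmask, lm)
  }
  # modal masks from the stacking order (larger index above)
  above <- function(i) {
    u <- matrix(0L, size, size)
    for (j in seq_len(n)) if (j > i) u <- pmax(u, amodal[[j]])
    pmax(u, dmask)
  }
  modal <- lapply(seq_len(n), function(i)
    as_mask(amodal[[i]] * (1L - above(i))))
  keep <- vapply(modal, function(m) sum(m) > 0, logical(1)) &
    vapply(amodal, function(m) sum(m) > 0, logical(1))
  idx <- which(keep)
  nk <- length(idx)
  Tm <- matrix(0L, nk, nk)
  for (ii in seq_len(nk)) for (jj in seq_len(nk)) {
    i <- idx[ii]; j <- idx[jj]
    if (i != j && sum(amodal[[i]] * amodal[[j]]) > 0) {
      Tm[ii, jj] <- if (i > j) 1L else -1L
    }
  }
  # validity: every overlapping pair keeps pair-exclusive overlap evidence
  valid <- TRUE
  hidden_frac <- numeric(0)
  for (ii in seq_len(nk)) for (jj in seq_len(nk)) {
    if (jj <= ii) next
    i <- idx[ii]; j <- idx[jj]
    ov <- amodal[[i]] * amodal[[j]]
    if (sum(ov) == 0) next
    excl <- ov
    for (k in idx) if (k != i && k != j) excl <- excl * (1L - amodal[[k]])
    excl <- excl * (1L - dmask)
    if (sum(excl) == 0) valid <- FALSE
    lower <- idx[min(ii, jj)]
    hidden_frac <- c(hidden_frac,
                     sum(ov) / min(sum(amodal[[i]]), sum(amodal[[j]])))
  }
  img <- .render_scene(spec, geoms[idx], amodal[idx], dlist)
  insts <- lapply(seq_len(nk), function(ii)
    instance_record(ii, modal[[idx[ii]]], amodal[[idx[ii]]]))
  sc <- scene_record(img, insts, order_matrix = Tm)
  attr(sc, "valid") <- valid && nk >= 1
  attr(sc, "achieved_overlap") <-
    if (length(hidden_frac)) mean(hidden_frac) else 0
  sc
}

.render_scene <- function(spec, geoms, amodal, dlist) {
  size <- spec$size
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  # foliage-like background with a soft gradient
  img <- array(0, c(size, size, 3))
  img[, , 1] <- 55 + 12 * xx / size
  img[, , 2] <- 85 + 20 * yy / size
  img[, , 3] <- 45 + 8 * xx / size
  # fruit drawn bottom of the stack first
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    m <- amodal[[i]] == 1L
    shade <- 1 - 0.4 * g$s[m]^1.6
    base <- c(195 + runif(1, -25, 25), 45 + runif(1, -15, 25),
              32 + runif(1, -10, 10))
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[m] <- base[ch] * shade
      img[, , ch] <- pl
    }
    # small specular highlight towards the upper-left of each fruit
    hl <- exp(-(((xx - g$cx + 0.3 * g$r)^2 +
                   (yy - g$cy + 0.3 * g$r)^2) / (0.15 * g$r^2)))
    for (ch in 1:3) img[, , ch][m] <- img[, , ch][m] + 60 * hl[m]
  }
  for (lm in dlist) {
    m <- lm == 1L
    base <- c(35 + runif(1, -10, 10), 95 + runif(1, -20, 20),
              30 + runif(1, -8, 8))
    for (ch in 1:3) img[, , ch][m] <- base[ch]
  }
  grad <- spec$illum * (xx + yy) / (2 * size) - spec$illum / 2
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] + grad +
      matrix(stats::rnorm(size * size, 0, spec$noise_sd), size, size)
  }
  array(round(pmin(pmax(img, 0), 255)), dim(img))
}

#' Generate a list of scenes
#'
#' @param spec a [scene_spec()].
#' @param n number of scenes.
#' @param seed master seed; scene `k` uses `seed + k`.
#' @return list of `scene_record`s.
#' @export
generate_scenes <- function(spec, n, seed = spec$seed) {
  lapply(seq_len(n), function(k) generate_scene(spec, seed = seed + k))
}

#' Build a bank of unoccluded object crops
#'
#' Each bank entry is a small image crop containing one fully visible
#' fruit together with its complete binary mask, suitable for cloning
#' into backgrounds with [compose_occlusion_dataset()].
#'
#' @param n number of bank objects.
#' @param spec a [scene_spec()] providing shape/radius/rendering options.
#' @param seed integer seed.
#' @return list of `list(image, mask)` entries.
#' @export
make_object_bank <- function(n, spec = scene_spec(), seed = 1L) {
  with_seed(seed, lapply(seq_len(n), function(k) {
    g <- .sample_instance_geometry(spec)
    side <- as.integer(ceiling(2 * max(g$a, g$b)) + 7)
    ras <- superellipse_raster(side, side / 2, side / 2, g$a, g$b, g$e,
                               g$phi)
    gg <- c(g, list(cy = side / 2, cx = side / 2, s = ras$s))
    sp <- spec; sp$size <- side; sp$noise_sd <- min(spec$noise_sd, 2)
    img <- .render_scene(sp, list(gg), list(ras$mask), list())
    list(image = img, mask = as_mask(ras$mask))
  }))
}

#' Compose an occlusion dataset by seamless cloning
#'
#' Clones unoccluded bank objects into background images with the
#' mean-value membrane compositor, in a randomized order that defines the
#' stacking: each placed object's amodal mask is its full bank mask (the
#' source of exact amodal ground truth), while its modal mask is the
#' amodal mask minus the union of later-placed objects. Scenes with zero
#' visible instances are dropped.
#'
#' @param object_bank bank from [make_object_bank()] (or compatible).
#' @param backgrounds list of `H x W x 3` background images (0..255).
#' @param spec a [scene_spec()]; `n_range` controls objects per scene.
#' @param seed integer seed.
#' @return list of `scene_record`s.
#' @export
compose_occlusion_dataset <- function(object_bank, backgrounds,
                                      spec = scene_spec(), seed = 1L) {
  if (length(object_bank) == 0) stop("object bank is empty")
  with_seed(seed, {
    scenes <- list()
    for (bg in backgrounds) {
      size_h <- dim(bg)[1]; size_w <- dim(bg)[2]
      k <- if (spec$n_range[1] == spec$n_range[2]) spec$n_range[1] else
        sample(seq(spec$n_range[1], spec$n_range[2]), 1)
      img <- bg
      amodal <- list()
      for (i in seq_len(k)) {
        ob <- object_bank[[sample.int(length(object_bank), 1)]]
        bb <- mask_bbox(ob$mask)
        placed <- FALSE
        for (try in 1:30) {
          dy <- sample.int(size_h, 1) - 1 - bb["y"] - round(bb["h"] / 2)
          dx <- sample.int(size_w, 1) - 1 - bb["x"] - round(bb["w"] / 2)
          top <- bb["y"] + dy; left <- bb["x"] + dx
          if (top >= 1 && left >= 1 && top + bb["h"] <= size_h - 1 &&
              left + bb["w"] <= size_w - 1) { placed <- TRUE; break }
        }
        if (!placed) next
        res <- mvc_clone_mask(ob$image, ob$mask, img,
                              offset = c(as.integer(dy), as.integer(dx)))
        img <- res$image
        amodal[[length(amodal) + 1L]] <- res$mask
      }
      n <- length(amodal)
      if (n == 0) next
      modal <- lapply(seq_len(n), function(i) {
        m <- amodal[[i]]
        for (j in seq_len(n)) if (j > i) m <- m * (1L - amodal[[j]])
        as_mask(m)
      })
      keep <- which(vapply(modal, sum, numeric(1)) > 0)
      if (length(keep) == 0) next
      nk <- length(keep)
      Tm <- matrix(0L, nk, nk)
      for (ii in seq_len(nk)) for (jj in seq_len(nk)) {
        i <- keep[ii]; j <- keep[jj]
        if (i != j && sum(amodal[[i]] * amodal[[j]]) > 0) {
          Tm[ii, jj] <- if (i > j) 1L else -1L
        }
      }
      insts <- lapply(seq_len(nk), function(ii)
        instance_record(ii, modal[[keep[ii]]], amodal[[keep[ii]]]))
      scenes[[length(scenes) + 1L]] <- scene_record(img, insts, Tm)
    }
    scenes
  })
}
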