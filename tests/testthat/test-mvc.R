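test_that("mean-value coordinates are a partition of unity with linear precision", {
  poly <- convex_polygon(14)
  set.seed(3)
  worst_sum <- 0; worst_lin <- 0
  for (k in 1:500) {
    x <- c(10, 10) + runif(2, -4, 4)
    lam <- mvc_coordinates(x, poly)
    expect_true(all(lam >= 0))  # convex polygon
    worst_sum <- max(worst_sum, abs(sum(lam) - 1))
    worst_lin <- max(worst_lin, sqrt(sum((colSums(lam * poly) - x)^2)))
  }
  expect_lt(worst_sum, 1e-10)
  expect_lt(worst_lin, 1e-8)
})

test_that("the centre of a square gets equal weights and near-vertex points concentrate", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  expect_equal(mvc_coordinates(c(0.5, 0.5), sq), rep(0.25, 4))
  lam <- mvc_coordinates(c(1e-4, 1e-4), sq)
  expect_gt(lam[1], 0.99)
})

test_that("boundary points are rejected", {
  sq <- rbind(c(0, 0), c(0, 2), c(2, 2), c(2, 0))
  expect_error(mvc_coordinates(c(0, 1), sq), "boundary")
  expect_error(mvc_coordinates(c(0, 0), sq), "boundary")
})

test_that("cloning with identical boundary data returns the source patch", {
  set.seed(4)
  src <- array(runif(21 * 21 * 3, 0, 255), c(21, 21, 3))
  mask <- disk_mask(21, 11, 11, 8)
  res <- mvc_clone_mask(src, mask, src, offset = c(0L, 0L))
  expect_equal(res$image, src)
})

test_that("a constant boundary offset shifts every interior pixel by that constant", {
  set.seed(5)
  src <- array(runif(21 * 21 * 3, 20, 200), c(21, 21, 3))
  mask <- disk_mask(21, 11, 11, 8)
  tgt <- src + 30
  res <- mvc_clone_mask(src, mask, tgt, offset = c(0L, 0L))
  inner <- mask * (1L - extract_boundary(mask))
  for (ch in 1:3) {
    expect_lt(max(abs((res$image[, , ch] - src[, , ch] - 30))[inner == 1]),
              1e-9)
  }
  # boundary pixels keep the target values exactly
  bnd <- extract_boundary(mask)
  for (ch in 1:3) {
    expect_equal(res$image[, , ch][bnd == 1], tgt[, , ch][bnd == 1])
  }
})

test_that("the MVC membrane tracks the harmonic membrane within 2 intensity levels", {
  mask <- disk_mask(21, 11, 11, 8)
  inner <- (mask * (1L - extract_boundary(mask))) == 1L
  mads <- numeric(0)
  for (trial in 1:20) {
    set.seed(400 + trial)
    yy <- row(mask); xx <- col(mask)
    diffb <- 20 * sin(yy / 3 + runif(1, 0, 6)) *
      cos(xx / 4 + runif(1, 0, 6)) + runif(1, -10, 10)
    src <- array(runif(1, 80, 150), c(21, 21, 3))
    tgt <- src
    for (ch in 1:3) tgt[, , ch] <- src[, , ch] + diffb
    res <- mvc_clone_mask(src, mask, tgt, offset = c(0L, 0L))
    oracle <- laplace_membrane(mask, diffb)
    got <- res$image[, , 1][inner] - src[, , 1][inner]
    mads <- c(mads, mean(abs(got - oracle[inner])))
  }
  expect_lt(mean(mads), 2)
  expect_lt(max(mads), 2)
})

test_that("placements outside the target bounds are rejected before compositing", {
  src <- flat_image(21, 21)
  mask <- disk_mask(21, 11, 11, 8)
  expect_error(mvc_clone_mask(src, mask, flat_image(21, 21),
                              offset = c(15L, 0L)),
               "exceeds target bounds")
})

test_that("composing from an object bank yields exact amodal ground truth", {
  sp <- scene_spec(seed = 6, n_range = c(2L, 3L))
  bank <- make_object_bank(6, sp, seed = 11)
  bgs <- lapply(1:4, function(i) flat_image(64, 64, 90))
  scenes <- compose_occlusion_dataset(bank, bgs, sp, seed = 12)
  expect_gt(length(scenes), 0)
  for (sc in scenes) {
    n <- length(sc$instances)
    expect_identical(sc$order_matrix, -t(sc$order_matrix))
    for (i in seq_len(n)) {
      inst <- sc$instances[[i]]
      expect_true(all(inst$modal <= inst$amodal))
      # invisible pixels are exactly those covered by higher instances
      hidden <- inst$amodal * (1L - inst$modal)
      cover <- matrix(0L, 64, 64)
      for (j in seq_len(n)) {
        if (sc$order_matrix[j, i] == 1L) {
          cover <- pmax(cover, sc$instances[[j]]$amodal)
        }
      }
      expect_true(all(hidden <= cover))
    }
  }
  scenes2 <- compose_occlusion_dataset(bank, bgs, sp, seed = 12)
  expect_identical(scenes[[1]]$image, scenes2[[1]]$image)
  expect_error(compose_occlusion_dataset(list(), bgs, sp, seed = 1),
               "empty")
})

test_that("a single cloned object is fully visible (modal == amodal)", {
  sp <- scene_spec(seed = 7, n_range = c(1L, 1L))
  bank <- make_object_bank(2, sp, seed = 3)
  scenes <- compose_occlusion_dataset(bank, list(flat_image(64, 64)),
                                      sp, seed = 4)
  expect_identical(scenes[[1]]$instances[[1]]$modal,
                   scenes[[1]]$instances[[1]]$amodal)
})
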