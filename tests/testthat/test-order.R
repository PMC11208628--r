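test_that("pixel increments are set-difference cardinalities", {
  expect_equal(pixel_increment(disk_mask(16, 8, 8, 5),
                               disk_mask(16, 8, 8, 5)), 0)
  set.seed(70)
  for (k in 1:100) {
    h <- sample(4:20, 1); w <- sample(4:20, 1)
    amodal <- random_mask(h, w)
    inner <- as_mask(amodal * random_mask(h, w))
    expect_equal(pixel_increment(amodal, inner),
                 sum(amodal == 1L & inner == 0L))
  }
  expect_error(pixel_increment(matrix(0L, 3, 3), matrix(1L, 3, 3)),
               "must contain")
})

test_that("the pairwise rule follows the increment comparison with ties to zero", {
  expect_identical(pairwise_order(0, 0), 0L)
  expect_identical(pairwise_order(3, 10), 1L)
  expect_identical(pairwise_order(10, 3), -1L)
  expect_identical(pairwise_order(5, 5), 0L)
  set.seed(71)
  for (k in 1:50) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    expect_identical(pairwise_order(a, b), -pairwise_order(b, a))
  }
})

test_that("ground-truth amodal masks reproduce the two-disk order", {
  sc <- two_disk_scene()
  g <- build_order_graph(sc, amodal_masks = lapply(sc$instances,
                                                   function(x) x$amodal))
  expect_identical(g$T, sc$order_matrix)
  # the top disk's pair increment is 0, the bottom's is the overlap size
})

test_that("oracle identity: ground-truth masks recover the generator graph exactly", {
  sp <- scene_spec(seed = 72)
  ok <- 0
  for (s in 1:20) {
    sc <- generate_scene(sp, seed = 800 + s)
    g <- build_order_graph(sc, amodal_masks = lapply(sc$instances,
                                                     function(x) x$amodal))
    expect_identical(g$T, sc$order_matrix)
    expect_identical(g$T, -t(g$T))
    ok <- ok + 1
  }
  expect_equal(ok, 20)
})

test_that("an empty scene gives an empty graph and one instance gives [[0]]", {
  sc0 <- scene_record(flat_image(16, 16), list())
  g0 <- build_order_graph(sc0, amodal_masks = list())
  expect_identical(dim(g0$T), c(0L, 0L))
  m <- disk_mask(16, 8, 8, 5)
  sc1 <- scene_record(flat_image(16, 16), list(instance_record(1L, m, m)))
  g1 <- build_order_graph(sc1, amodal_masks = list(m))
  expect_identical(g1$T, matrix(0L, 1, 1))
})

test_that("heuristic baselines order by area and by bounding-box bottom", {
  size <- 48
  big <- disk_mask(size, 20, 16, 12)
  small <- disk_mask(size, 20, 30, 7)
  sc <- scene_record(flat_image(size, size),
                     list(instance_record(1L, as_mask(big * (1L - small)),
                                          big),
                          instance_record(2L, small, small)))
  ga <- baseline_order(sc, "area")
  expect_identical(ga$T[1, 2], 1L)  # larger area in front
  # y-axis: lower bottom edge in front
  lowdisk <- disk_mask(size, 36, 20, 8)
  highdisk <- disk_mask(size, 14, 26, 8)
  sc2 <- scene_record(flat_image(size, size),
                      list(instance_record(1L, lowdisk, lowdisk),
                           instance_record(2L, highdisk, highdisk)))
  # make them adjacent by dilated modal overlap
  mid1 <- disk_mask(size, 28, 22, 9); mid2 <- disk_mask(size, 22, 24, 9)
  sc3 <- scene_record(flat_image(size, size),
                      list(instance_record(1L, as_mask(mid1 * (1L - mid2)),
                                           mid1),
                           instance_record(2L, mid2, mid2)))
  gy <- baseline_order(sc3, "yaxis")
  b1 <- mask_bbox(sc3$instances[[1]]$modal)
  b2 <- mask_bbox(sc3$instances[[2]]$modal)
  want <- if (b1["y"] + b1["h"] > b2["y"] + b2["h"]) 1L else
    if (b1["y"] + b1["h"] < b2["y"] + b2["h"]) -1L else 0L
  expect_identical(gy$T[1, 2], want)
  # equal keys tie to zero
  twin1 <- disk_mask(size, 24, 18, 8); twin2 <- mask_shift(twin1, 0, 10)
  sc4 <- scene_record(flat_image(size, size),
                      list(instance_record(1L, twin1, twin1),
                           instance_record(2L, twin2, twin2)))
  expect_identical(baseline_order(sc4, "area")$T[1, 2], 0L)
})

test_that("every emitted graph is antisymmetric with zero diagonal", {
  sp <- scene_spec(seed = 73)
  for (s in 1:5) {
    sc <- generate_scene(sp, seed = 900 + s)
    for (g in list(build_order_graph(sc, amodal_masks =
                                       lapply(sc$instances,
                                              function(x) x$amodal)),
                   baseline_order(sc, "area"),
                   baseline_order(sc, "yaxis"))) {
      expect_identical(g$T, -t(g$T))
      expect_true(all(diag(g$T) == 0L))
    }
  }
})
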