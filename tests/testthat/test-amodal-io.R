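test_that("RLE codec follows the column-major zeros-first convention", {
  z <- matrix(0L, 4, 4)
  expect_identical(rle_encode(z)$counts, 16L)
  o <- matrix(1L, 2, 2)
  expect_identical(rle_encode(o)$counts, c(0L, 4L))
  expect_identical(rle_decode(rle_encode(z)), z)
  expect_identical(rle_decode(rle_encode(o)), o)
  # column-major: a single foreground pixel at (1,2) of a 2x2 mask sits
  # after the two pixels of column 1
  m <- matrix(c(0L, 0L, 1L, 0L), 2, 2)
  expect_identical(rle_encode(m)$counts, c(2L, 1L, 1L))
})

test_that("RLE round-trip is bit-exact for random masks of many sizes", {
  set.seed(11)
  for (k in 1:200) {
    h <- sample(1:64, 1); w <- sample(1:64, 1)
    m <- random_mask(h, w)
    expect_identical(rle_decode(rle_encode(m)), as_mask(m))
  }
})

test_that("malformed RLE counts raise an error naming the annotation", {
  bad <- list(size = c(4, 4), counts = c(10L, 3L))
  expect_error(rle_decode(bad, annotation_id = 77), "annotation id 77")
  expect_error(rle_decode(bad), "malformed RLE")
})

test_that("mask bbox is the tight half-open box in 0-based pixels", {
  m <- matrix(0L, 8, 8); m[3:5, 2:7] <- 1L
  expect_equal(unname(mask_bbox(m)), c(1, 2, 6, 3))
  expect_equal(unname(mask_bbox(matrix(0L, 3, 3))), c(0, 0, 0, 0))
})

test_that("boundary extraction matches mask minus cross-eroded mask", {
  m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L
  expect_equal(sum(extract_boundary(m)), 16)
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_identical(extract_boundary(one), one)
  expect_equal(sum(extract_boundary(matrix(0L, 4, 4))), 0)
})

test_that("dataset read/write round-trips scenes bit-exactly", {
  sp <- scene_spec(seed = 21)
  scenes <- generate_scenes(sp, 5, seed = 300)
  d <- withr::local_tempdir()
  write_dataset(scenes, d)
  rd <- read_dataset(d)
  expect_length(rd, 5)
  for (k in seq_along(scenes)) {
    expect_identical(rd[[k]]$order_matrix, scenes[[k]]$order_matrix)
    expect_identical(rd[[k]]$image, scenes[[k]]$image)
    for (i in seq_along(scenes[[k]]$instances)) {
      expect_identical(rd[[k]]$instances[[i]]$modal,
                       scenes[[k]]$instances[[i]]$modal)
      expect_identical(rd[[k]]$instances[[i]]$amodal,
                       scenes[[k]]$instances[[i]]$amodal)
    }
  }
})

test_that("empty dataset and modal==amodal single instance round-trip", {
  d <- withr::local_tempdir()
  write_dataset(list(), d)
  expect_length(read_dataset(d), 0)
  m <- disk_mask(16, 8, 8, 5)
  sc <- scene_record(flat_image(16, 16), list(instance_record(1L, m, m)))
  d2 <- withr::local_tempdir()
  write_dataset(list(sc), d2)
  rd <- read_dataset(d2)
  expect_identical(rd[[1]]$instances[[1]]$modal,
                   rd[[1]]$instances[[1]]$amodal)
})

test_that("annotations referencing a missing image id are rejected", {
  d <- withr::local_tempdir()
  m <- disk_mask(8, 4, 4, 2)
  sc <- scene_record(flat_image(8, 8), list(instance_record(1L, m)))
  write_dataset(list(sc), d)
  obj <- jsonlite::read_json(file.path(d, "annotations.json"))
  obj$annotations[[1]]$image_id <- 99
  jsonlite::write_json(obj, file.path(d, "annotations.json"),
                       auto_unbox = TRUE)
  expect_error(read_dataset(d), "missing image id")
})

test_that("a modal mask exceeding its amodal mask triggers a warning", {
  modal <- disk_mask(16, 8, 8, 6)
  amodal <- disk_mask(16, 8, 8, 4)
  expect_warning(instance_record(3L, modal, amodal), "not a subset")
})

test_that("dataset splitting gives 810/90/100 on the canonical sizes", {
  s <- split_dataset(1000, 100, c(9, 1), seed = 4)
  expect_length(s$train_ids, 810)
  expect_length(s$val_ids, 90)
  expect_length(s$test_ids, 100)
  expect_length(intersect(s$train_ids, s$val_ids), 0)
  expect_length(intersect(s$train_ids, s$test_ids), 0)
  expect_setequal(c(s$train_ids, s$val_ids, s$test_ids), 1:1000)
})

test_that("splitting is deterministic, covers all ids, floors odd ratios", {
  s1 <- split_dataset(10, 0, c(1, 1), seed = 2)
  expect_length(s1$train_ids, 5)
  expect_length(s1$val_ids, 5)
  expect_length(s1$test_ids, 0)
  s2 <- split_dataset(10, 0, c(1, 1), seed = 2)
  expect_identical(s1, s2)
  set.seed(31)
  for (k in 1:20) {
    n <- sample(5:200, 1); nt <- sample(0:(n - 2), 1)
    r <- c(sample(1:9, 1), sample(1:9, 1))
    s <- suppressMessages(split_dataset(n, nt, r, seed = k))
    expect_setequal(c(s$train_ids, s$val_ids, s$test_ids), seq_len(n))
    expect_length(s$test_ids, nt)
    # train takes the floor of the larger ratio share
    expect_length(s$train_ids,
                  floor((n - nt) * max(r) / sum(r)))
  }
})

test_that("augmentation multiplies the set and preserves binary masks", {
  sp <- scene_spec(seed = 8)
  scenes <- generate_scenes(sp, 4, seed = 50)
  aug <- augment_training_set(scenes, 3, seed = 1)
  expect_length(aug, 12)
  for (sc in aug) {
    for (inst in sc$instances) expect_true(is_valid_mask(inst$modal))
  }
  ident <- augment_training_set(scenes, 1, seed = 1,
                                transforms = character(0))
  expect_identical(ident[[1]]$image, scenes[[1]]$image)
})

test_that("flip is an involution and flip/translation keep pixel counts", {
  sp <- scene_spec(seed = 9)
  sc <- generate_scene(sp)
  f2 <- scene_flip(scene_flip(sc))
  for (i in seq_along(sc$instances)) {
    expect_identical(f2$instances[[i]]$modal, sc$instances[[i]]$modal)
  }
  fl <- scene_flip(sc)
  tr <- scene_translate(sc, 2, -3)
  for (i in seq_along(sc$instances)) {
    expect_equal(sum(fl$instances[[i]]$modal),
                 sum(sc$instances[[i]]$modal))
    # small translations keep in-frame instances intact
    inb <- sum(sc$instances[[i]]$modal[3:62, 4:64])
    expect_gte(sum(tr$instances[[i]]$modal), inb)
  }
})

test_that("crop windows larger than the image are rejected", {
  sp <- scene_spec(seed = 10)
  sc <- generate_scene(sp)
  expect_error(scene_crop(sc, 0, 0, 100, 100), "crop window")
})
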