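test_that("split sizes reproduce the published per-class subset counts", {
  for (seed in c(1, 7, 123)) {
    a <- split_class(2244, seed = seed)
    expect_identical(lengths(a)[c("train", "val", "test")],
                     c(train = 1202L, val = 301L, test = 741L))
    b <- split_class(12846, seed = seed)
    expect_identical(lengths(b)[c("train", "val", "test")],
                     c(train = 6884L, val = 1722L, test = 4240L))
  }
})

test_that("ceiling convention on held-out counts (n = 10)", {
  s <- split_class(10, seed = 1)
  expect_identical(lengths(s)[c("train", "val", "test")],
                   c(train = 4L, val = 2L, test = 4L))
})

test_that("splits are disjoint, exhaustive, and seed-dependent in membership", {
  s <- split_class(100, seed = 1)
  all_items <- sort(c(s$train, s$val, s$test))
  expect_identical(all_items, 1:100)
  s2 <- split_class(100, seed = 2)
  expect_false(identical(sort(s$test), sort(s2$test)))
  # same seed, same membership
  expect_identical(split_class(100, seed = 1), s)
})

test_that("degenerate splits are rejected", {
  expect_error(split_class(2), "at least 3")
  expect_error(split_class(100, test_frac = 0), "fractions")
})

test_that("build_manifest assigns ids by lexicographic folder order", {
  root <- file.path(tempdir(), "manroot")
  unlink(root, recursive = TRUE)
  for (cl in c("longitudinal_division", "other_division")) {
    dir.create(file.path(root, cl), recursive = TRUE)
    for (i in 1:3)
      png::writePNG(matrix(runif(16), 4),
                    file.path(root, cl, sprintf("img%d.png", i)))
  }
  writeLines("not an image", file.path(root, "other_division", "notes.txt"))
  expect_warning(man <- build_manifest(root), "non-image")
  expect_identical(nrow(man), 6L)
  expect_identical(unique(man$class_id[man$class_name ==
                                         "longitudinal_division"]), 0L)
  expect_identical(unique(man$class_id[man$class_name ==
                                         "other_division"]), 1L)
  solo <- file.path(tempdir(), "manroot_solo")
  dir.create(file.path(solo, "only_class"), recursive = TRUE,
             showWarnings = FALSE)
  expect_error(build_manifest(solo), "class folders")
})

test_that("assign_splits stratifies within each class", {
  man <- tiny_crop_manifest()
  for (cid in 0:1) {
    sub <- man[man$class_id == cid, ]
    expect_identical(sort(unique(sub$split)), c("test", "train", "val"))
    expect_identical(nrow(sub),
                     sum(table(sub$split)))
    # 16 items: test = ceil(16*.33) = 6, val = ceil(10*.2) = 2, train = 8
    expect_identical(as.integer(table(sub$split)[c("train", "val", "test")]),
                     c(8L, 2L, 6L))
  }
})

test_that("augment output is always a normalized 128x128x3 array", {
  set.seed(2)
  img <- matrix(runif(50 * 70), 50, 70)
  out <- augment(img, augment_spec(), training = TRUE)
  expect_identical(dim(out), c(128L, 128L, 3L))
  expect_true(all(is.finite(out)))
})

test_that("no-op augmentation equals resize + normalize", {
  set.seed(3)
  img <- matrix(runif(40 * 40), 40, 40)
  spec <- augment_spec(rotation = 0, hflip_prob = 0, vflip_prob = 0,
                       normalize_mean = rep(0.5, 3),
                       normalize_std = rep(0.5, 3))
  a <- augment(img, spec, training = TRUE)
  b <- augment(img, spec, training = FALSE)
  expect_identical(a, b)
  r <- resize_bilinear(img, 128, 128)
  expect_equal(a[, , 1], (r - 0.5) / 0.5)
})

test_that("a constant image normalizes to the closed form (c - m)/s", {
  img <- matrix(0.7, 30, 30)
  spec <- augment_spec(normalize_mean = c(0.485, 0.456, 0.406),
                       normalize_std = c(0.229, 0.224, 0.225))
  set.seed(1)
  out <- augment(img, spec, training = TRUE)
  for (ch in 1:3)
    expect_equal(unique(as.vector(round(out[, , ch], 10))),
                 round((0.7 - spec$normalize_mean[ch]) /
                         spec$normalize_std[ch], 10))
  expect_error(augment(matrix(numeric(0), 0, 0), spec), "degenerate")
})

test_that("resize_bilinear is exact on identity and constant inputs", {
  img <- matrix(runif(64), 8, 8)
  expect_equal(resize_bilinear(img, 8, 8), img)
  expect_equal(resize_bilinear(matrix(0.3, 5, 9), 12, 4),
               matrix(0.3, 12, 4))
})

test_that("rotation by 0 and 360 degrees preserves the image", {
  set.seed(4)
  img <- matrix(runif(25 * 25), 25, 25)
  expect_equal(rotate_image(img, 0), img)
  expect_equal(rotate_image(img, 360), img, tolerance = 1e-8)
})
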