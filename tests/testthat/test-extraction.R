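test_that("binarize treats dark pixels as foreground", {
  img <- matrix(0, 4, 4)
  expect_true(all(binarize(img, threshold = 0.5)))
  expect_error(binarize(img, threshold = "otsu"), "constant")
  expect_error(binarize(img, threshold = 1.5), "threshold")
})

test_that("invert flips the foreground convention exactly", {
  set.seed(1)
  img <- matrix(runif(100), 10, 10)  # no ties against 0.5 a.s.
  a <- binarize(img, 0.5, invert = FALSE)
  b <- binarize(img, 0.5, invert = TRUE)
  expect_identical(a, !b)
})

test_that("Otsu recovers the rendered foreground within 10%", {
  canvas <- matrix(0.88, 96, 96)
  out <- render_cell(canvas, cell_spec(c(48, 48), 36, 20, orientation = 1,
                                       septum = "longitudinal"))
  set.seed(4)
  img <- pmin(pmax(out + matrix(rnorm(96 * 96, 0, 0.03), 96), 0), 1)
  bw <- binarize(img, "otsu")
  expect_equal(sum(bw), sum(attr(out, "mask")), tolerance = 0.1)
})

test_that("connectivity semantics: diagonal pixels", {
  bin <- matrix(FALSE, 4, 4)
  bin[2, 2] <- TRUE; bin[3, 3] <- TRUE
  expect_identical(attr(label_components(bin, 8), "n_components"), 1L)
  expect_identical(attr(label_components(bin, 4), "n_components"), 2L)
  empty <- matrix(FALSE, 3, 3)
  expect_identical(attr(label_components(empty, 8), "n_components"), 0L)
})

test_that("labeling agrees with a recursive flood-fill oracle", {
  set.seed(12)
  for (conn in c(4L, 8L)) {
    for (rep in 1:5) {
      bin <- matrix(runif(32 * 32) < 0.35, 32, 32)
      lab <- label_components(bin, conn)
      oracle <- floodfill_labels(bin, conn)
      expect_identical(attr(lab, "n_components"), max(oracle))
      # identical partitions: co-labeled pairs must match
      expect_identical(as.vector(lab != 0), as.vector(oracle != 0))
      key <- paste(lab[lab > 0], oracle[oracle > 0])
      expect_identical(length(unique(key)), max(oracle))
    }
  }
})

test_that("ids are assigned in raster-scan order of first pixel", {
  bin <- matrix(FALSE, 5, 7)
  bin[4, 2] <- TRUE      # later in raster order (row 4)
  bin[1, 6] <- TRUE      # first row, so first id
  bin[2, 3] <- TRUE
  lab <- label_components(bin, 8)
  expect_identical(lab[1, 6], 1L)
  expect_identical(lab[2, 3], 2L)
  expect_identical(lab[4, 2], 3L)
})

test_that("bounding boxes are tight, ordered and area-filtered", {
  bin <- matrix(FALSE, 10, 12)
  bin[3:5, 6:8] <- TRUE                      # 3x3 block, rows 2-4 cols 5-7
  lab <- label_components(bin, 8)
  bb <- bounding_boxes(lab, min_area = 0)
  expect_identical(unlist(bb[1, c("row0", "col0", "row1", "col1")],
                          use.names = FALSE), c(2L, 5L, 5L, 8L))
  expect_identical(bb$area, 9L)

  # filtering: components of area 4 and 120
  bin2 <- matrix(FALSE, 30, 30)
  bin2[2:3, 2:3] <- TRUE            # area 4
  bin2[10:21, 5:14] <- TRUE         # area 120
  lab2 <- label_components(bin2, 8)
  expect_identical(nrow(bounding_boxes(lab2, min_area = 50)), 1L)
  expect_identical(nrow(bounding_boxes(lab2, min_area = 0)),
                   attr(lab2, "n_components"))
})

test_that("component areas conserve the foreground pixel count", {
  set.seed(3)
  bin <- matrix(runif(40 * 40) < 0.3, 40, 40)
  bb <- bounding_boxes(label_components(bin, 8), min_area = 0)
  expect_identical(sum(bb$area), sum(bin))
})

test_that("flipping the image flips the boxes correspondingly", {
  set.seed(8)
  bin <- matrix(runif(20 * 24) < 0.2, 20, 24)
  bb <- bounding_boxes(label_components(bin, 8), 0)
  fl <- bounding_boxes(label_components(bin[20:1, ], 8), 0)
  expect_setequal(paste(20 - bb$row1, bb$col0, 20 - bb$row0, bb$col1),
                  paste(fl$row0, fl$col0, fl$row1, fl$col1))
})

test_that("crops reproduce source intensities and clip at borders", {
  set.seed(5)
  img <- matrix(runif(100), 10, 10)
  dir <- file.path(tempdir(), "crops1")
  boxes <- data.frame(row0 = 2, col0 = 5, row1 = 5, col1 = 8)
  p <- extract_crops(img, boxes, dir, padding = 0, stem = "t")
  crop <- png::readPNG(p[1])
  expect_identical(dim(crop), c(3L, 3L))
  expect_equal(crop, img[3:5, 6:8], tolerance = 1 / 255)

  # corner box with padding 2 clips to bounds
  boxes2 <- data.frame(row0 = 0, col0 = 0, row1 = 3, col1 = 3)
  p2 <- extract_crops(img, boxes2, dir, padding = 2, stem = "u")
  expect_identical(dim(png::readPNG(p2[1])), c(5L, 5L))
})

test_that("pipeline composition recovers every planted cell with IoU >= 0.8", {
  cfg <- synth_config(canvas = c(200, 200), background_noise_sd = 0.03,
                      seed = 1)
  set.seed(21)
  res <- generate_microscope_image(cfg, "longitudinal_division", 5)
  bw <- binarize(res$image, "otsu")
  bb <- bounding_boxes(label_components(bw, 8), min_area = 50)
  expect_identical(nrow(bb), 5L)
  for (i in seq_len(5)) {
    truth <- as.numeric(res$truth[i, c("row0", "col0", "row1", "col1")])
    ious <- apply(bb[, c("row0", "col0", "row1", "col1")], 1, iou_box,
                  b = truth)
    expect_gte(max(ious), 0.8)
  }
})

test_that("extract_cells exports one crop per planted cell", {
  man <- tiny_crop_manifest()
  # 8 images x 2 cells per class
  expect_identical(sum(man$class_id == 0), 16L)
  expect_identical(sum(man$class_id == 1), 16L)
})
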