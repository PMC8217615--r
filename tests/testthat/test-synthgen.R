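test_that("cell_spec enforces its geometric invariants", {
  expect_s3_class(cell_spec(c(30, 30), 20, 10), "cell_spec")
  expect_error(cell_spec(c(30, 30), 10, 20), "length")
  expect_error(cell_spec(c(30, 30), 20, 2), "width")
  expect_error(cell_spec(c(30, 30), 20, 10, crease_width = 12), "crease")
  expect_error(cell_spec(c(30, 30), 20, 10, orientation = pi), "orientation")
})

test_that("a rendered rod is a single connected component", {
  canvas <- matrix(0.9, 64, 64)
  out <- render_cell(canvas, cell_spec(c(32, 32), 30, 12,
                                       orientation = 0.6))
  mask <- attr(out, "mask")
  lab <- floodfill_labels(mask, 8)
  expect_identical(max(lab), 1L)
})

test_that("rendered aspect ratio matches the spec (pixel-scan measurement)", {
  canvas <- matrix(0.9, 80, 80)
  out <- render_cell(canvas, cell_spec(c(40, 40), 30, 20, orientation = 0))
  mask <- attr(out, "mask")
  fg <- which(mask, arr.ind = TRUE)
  # orientation 0: major axis along rows; brute-force extent scan
  len <- diff(range(fg[, 1])) + 1
  wid <- diff(range(fg[, 2])) + 1
  expect_equal(len / wid, 1.5, tolerance = 0.1)
  expect_equal(len, 30, tolerance = 2)
})

test_that("a narrow crease keeps the mask 8-connected", {
  canvas <- matrix(0.9, 64, 64)
  for (orient in c(0, 0.8, 2.2)) {
    out <- render_cell(canvas, cell_spec(c(32, 32), 34, 12,
                                         orientation = orient,
                                         crease_width = 2))
    lab <- floodfill_labels(attr(out, "mask"), 8)
    expect_identical(max(lab), 1L)
  }
})

test_that("rendering rejects cells that do not fit the canvas", {
  canvas <- matrix(0.9, 40, 40)
  expect_error(render_cell(canvas, cell_spec(c(5, 20), 30, 12)), "fit")
})

test_that("generate_microscope_image honors the cell count and ground truth", {
  cfg <- synth_config(canvas = c(200, 200), seed = 1)
  set.seed(10)
  res <- generate_microscope_image(cfg, "longitudinal_division", n_cells = 5)
  expect_identical(nrow(res$truth), 5L)
  expect_true(all(res$truth$class_id == 0L))
  # boxes lie within the canvas
  expect_true(all(res$truth$row0 >= 0 & res$truth$col0 >= 0))
  expect_true(all(res$truth$row1 <= 200 & res$truth$col1 <= 200))
  # boxes are pairwise disjoint (overlap is forbidden by construction)
  for (i in seq_len(4)) for (j in (i + 1):5) {
    a <- as.numeric(res$truth[i, -1]); b <- as.numeric(res$truth[j, -1])
    expect_equal(iou_box(a, b), 0)
  }
})

test_that("image generation is deterministic given the RNG state", {
  cfg <- synth_config(canvas = c(160, 160), seed = 1)
  set.seed(77); a <- generate_microscope_image(cfg, "other_division", 3)
  set.seed(77); b <- generate_microscope_image(cfg, "other_division", 3)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("with zero noise the image equals the clean render", {
  cfg <- synth_config(canvas = c(120, 120), background_noise_sd = 0,
                      seed = 1)
  set.seed(5)
  res <- generate_microscope_image(cfg, "other_division", 1)
  # re-render the same cell: same RNG draws
  set.seed(5)
  res2 <- generate_microscope_image(cfg, "other_division", 1)
  expect_identical(res$image, res2$image)
  # background pixels are exactly the configured level
  expect_identical(max(res$image), cfg$background)
})

test_that("an overcrowded canvas fails with an informative error", {
  cfg <- synth_config(canvas = c(64, 64), seed = 1)
  set.seed(2)
  expect_error(generate_microscope_image(cfg, "other_division", 30,
                                         max_retries = 10),
               "retries")
})

test_that("generate_dataset writes per-class folders, counts and manifest", {
  dir <- file.path(tempdir(), "synds")
  unlink(dir, recursive = TRUE)
  cfg <- synth_config(images_per_class = 3, cells_per_image = c(2, 3),
                      canvas = c(160, 160), seed = 42)
  man <- generate_dataset(cfg, dir)
  expect_identical(length(list.files(file.path(dir, "longitudinal_division"),
                                     pattern = "png$")), 3L)
  expect_identical(length(list.files(file.path(dir, "other_division"),
                                     pattern = "png$")), 3L)
  expect_true(all(man$class_id %in% c(0L, 1L)))
  expect_true(all(file.exists(man$path)))
  # one manifest row per planted cell, 2-3 cells per image
  expect_true(nrow(man) >= 12 && nrow(man) <= 18)
})

test_that("regeneration with the same seed is byte-identical", {
  d1 <- file.path(tempdir(), "synds_a"); d2 <- file.path(tempdir(), "synds_b")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- synth_config(images_per_class = 2, canvas = c(160, 160), seed = 3)
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("the two classes are separable by a simple held-out classifier", {
  # a small classifier on crude shape moments of the binarized crops must
  # already separate the classes; the network only has to do better
  man <- tiny_crop_manifest()
  feats <- t(vapply(man$path, function(p) {
    img <- read_image(p)
    bw <- binarize(img, 0.55)
    fg <- which(bw, arr.ind = TRUE)
    if (nrow(fg) < 5) return(c(0.5, 0))
    ev <- eigen(cov(fg), only.values = TRUE)$values
    c(sqrt(max(ev[2], 0) / ev[1]), mean(bw))
  }, numeric(2)))
  df <- data.frame(y = man$class_id, r = feats[, 1], f = feats[, 2])
  tr <- man$split != "test"
  fitg <- suppressWarnings(glm(y ~ r + f, binomial, df[tr, ]))
  pred <- as.integer(predict(fitg, df[!tr, ], type = "response") > 0.5)
  expect_gte(mean(pred == df$y[!tr]), 0.95)
})
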