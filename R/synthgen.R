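#' Describe one synthetic bacterial cell
#'
#' A cell is rendered as a capsule (a rectangle with semicircular caps) of a
#' given length, width and orientation. Dividing cells carry a septum: a
#' lighter contrast line along the major axis for longitudinal fission, or
#' across it for ordinary transverse division. A narrow transverse crease
#' (an indentation pinching the outline from both sides) emulates the
#' adversarial "very narrow crease" morphology that can be mistaken for a
#' longitudinal split.
#'
#' @param center numeric length-2, (row, col) pixel center.
#' @param length,width cell dimensions in pixels; `length >= width >= 3`.
#' @param orientation major-axis angle in radians, in `[0, pi)`.
#' @param septum one of `"none"`, `"longitudinal"`, `"transverse"`.
#' @param crease_width transverse crease width in pixels (0 = no crease);
#'   must be smaller than `width`.
#' @param intensity foreground gray level in `[0, 1]` (cells are dark on a
#'   light background).
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(center, length, width, orientation = 0,
                      septum = c("none", "longitudinal", "transverse"),
                      crease_width = 0, intensity = 0.2) {
  septum <- match.arg(septum)
  if (width < 3) stop("cell width must be at least 3 px")
  if (length < width) stop("cell length must be >= width")
  if (crease_width >= width) stop("crease_width must be smaller than width")
  if (orientation < 0 || orientation >= pi)
    stop("orientation must lie in [0, pi)")
  if (intensity < 0 || intensity > 1) stop("intensity must be in [0, 1]")
  structure(list(center = as.numeric(center), length = length, width = width,
                 orientation = orientation, septum = septum,
                 crease_width = crease_width, intensity = intensity),
            class = "cell_spec")
}

#' Configuration for the synthetic dataset generator
#'
#' The generator emulates phase-contrast microscope images: dark rod-shaped
#' cells on a light noisy background, several per image, all from one class
#' per image. Class 0 (`longitudinal_division`) cells are wide relative to
#' their length and carry an axial septum; class 1 (`other_division`) cells
#' are plain rods, rods with a transverse septum, or rods with a narrow
#' transverse crease (the adversarial negatives).
#'
#' @param images_per_class number of microscope images per class.
#' @param cells_per_image length-2 integer range (min, max) of cells per
#'   image (a single value fixes the count).
#' @param canvas `(height, width)` in pixels, each at least 64.
#' @param background level of the light background in `[0,1]`.
#' @param background_noise_sd standard deviation of additive Gaussian
#'   background noise, in intensity units.
#' @param invert render bright cells on a dark background instead.
#' @param class_geometry named list with elements `longitudinal_division`
#'   and `other_division`, each a list of sampling bounds (see
#'   [default_class_geometry()]).
#' @param seed integer seed controlling all sampling.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(images_per_class = 50,
                         cells_per_image = c(3, 6),
                         canvas = c(256, 256),
                         background = 0.88,
                         background_noise_sd = 0.03,
                         invert = FALSE,
                         class_geometry = default_class_geometry(),
                         seed = 1L) {
  if (any(canvas < 64)) stop("canvas dimensions must be at least 64 px")
  if (images_per_class < 1) stop("images_per_class must be >= 1")
  if (length(cells_per_image) == 1) cells_per_image <- rep(cells_per_image, 2)
  if (background_noise_sd < 0) stop("background_noise_sd must be >= 0")
  geo <- unlist(class_geometry)
  if (any(!is.finite(geo))) stop("class_geometry bounds must all be finite")
  structure(list(images_per_class = as.integer(images_per_class),
                 cells_per_image = as.integer(cells_per_image),
                 canvas = as.integer(canvas), background = background,
                 background_noise_sd = background_noise_sd, invert = invert,
                 class_geometry = class_geometry, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default per-class geometry distributions
#'
#' Longitudinally dividing cells widen instead of elongating, so the
#' longitudinal class samples width/length ratios above 0.55 and always
#' carries an axial septum; the other class samples ratios below 0.45 with a
#' mix of plain rods, transverse septa, and narrow-crease rods. Bounds are
#' uniform-sampling ranges in pixels (or radians for orientation).
#'
#' @return Named list of per-class sampling bounds.
#' @export
default_class_geometry <- function() {
  list(
    longitudinal_division = list(
      length = c(34, 48), width_ratio = c(0.58, 0.75),
      septum_probs = c(longitudinal = 1, transverse = 0, none = 0),
      crease_prob = 0, crease_width = c(2, 3),
      intensity = c(0.15, 0.3),
      orientation = list(c(15, 75), c(105, 165))),
    other_division = list(
      length = c(36, 60), width_ratio = c(0.25, 0.42),
      septum_probs = c(longitudinal = 0, transverse = 0.5, none = 0.5),
      crease_prob = 0.25, crease_width = c(2, 3),
      intensity = c(0.15, 0.3),
      orientation = list(c(15, 75), c(105, 165))))
}

# Orientation is drawn from bands (degrees) that keep cells away from exact
# axis alignment: classification operates on bounding-box crops resized to a
# fixed square, and a near-axis-aligned rod's box degenerates under that
# stretch (the apparent major axis can flip), destroying the morphology the
# classes are defined by.
sample_orientation <- function(bands) {
  b <- bands[[sample.int(length(bands), 1)]]
  runif(1, b[1], b[2]) * pi / 180
}

#' Render one cell onto a canvas
#'
#' Draws the capsule described by `spec` onto the intensity raster, with a
#' one-pixel anti-aliased edge. The septum is drawn as a lighter line inside
#' the cell body (stopping short of the poles so the binarized mask stays a
#' single connected component); a crease replaces outline pixels near the
#' cell midline with background from both sides, leaving the center joined.
#'
#' @param canvas numeric matrix in `[0,1]`; modified copy is returned.
#' @param spec a [cell_spec()].
#' @param background background level used for crease fill (defaults to the
#'   canvas median).
#' @return The canvas with the cell drawn, with attribute `"box"` holding
#'   the tight 0-based half-open bounding box `c(row0, col0, row1, col1)` of
#'   the rendered foreground and `"mask"` holding its logical mask.
#' @export
render_cell <- function(canvas, spec, background = NULL) {
  stopifnot(inherits(spec, "cell_spec"))
  H <- nrow(canvas); W <- ncol(canvas)
  if (is.null(background)) background <- median(canvas)
  hl <- spec$length / 2; hw <- spec$width / 2
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  # Work on the minimal patch that can contain the rotated capsule.
  rad <- hl + 2
  r0 <- max(1, floor(spec$center[1] - rad)); r1 <- min(H, ceiling(spec$center[1] + rad))
  c0 <- max(1, floor(spec$center[2] - rad)); c1 <- min(W, ceiling(spec$center[2] + rad))
  if (spec$center[1] - rad < 0 || spec$center[1] + rad > H + 1 ||
      spec$center[2] - rad < 0 || spec$center[2] + rad > W + 1)
    stop("cell_spec does not fit inside the canvas")
  rr <- r0:r1; cc <- c0:c1
  dr <- rr - spec$center[1]
  dc <- cc - spec$center[2]
  # Axis coordinates: u along the major axis, v across it. Orientation is the
  # angle of the major axis in (row, col) space.
  u <- outer(dr, dc, function(y, x) y * co + x * si)
  v <- outer(dr, dc, function(y, x) -y * si + x * co)
  ucl <- pmax(abs(u) - (hl - hw), 0)
  d <- sqrt(ucl^2 + v^2)                 # distance to capsule spine envelope
  cover <- clamp01(hw + 0.5 - d)         # 1 inside, 0 outside, ramp on edge
  val <- spec$intensity
  # septum gray level: clearly lighter than the cell body but still well
  # below any plausible binarization threshold, so the mask stays whole
  sep_val <- min(spec$intensity + 0.3, 0.5, background - 0.25)
  if (spec$septum == "longitudinal") {
    sep <- abs(v) <= 1 & abs(u) <= (hl - hw)
    val <- ifelse(sep, sep_val, spec$intensity)
  } else if (spec$septum == "transverse") {
    sep <- abs(u) <= 1 & abs(v) <= (hw - 2)
    val <- ifelse(sep, sep_val, spec$intensity)
  }
  if (spec$crease_width > 0) {
    # Pinch inward from both sides at the midline, keeping a joined core.
    core <- max(1.5, hw / 3)
    crease <- abs(u) <= spec$crease_width / 2 & abs(v) >= core
    cover[crease] <- 0
  }
  patch <- canvas[rr, cc, drop = FALSE]
  newpatch <- patch * (1 - cover) + val * cover
  out <- canvas
  out[rr, cc] <- newpatch
  mask <- matrix(FALSE, H, W)
  mask[rr, cc] <- cover >= 0.5
  fg <- which(mask, arr.ind = TRUE)
  box <- c(min(fg[, 1]) - 1L, min(fg[, 2]) - 1L, max(fg[, 1]), max(fg[, 2]))
  attr(out, "box") <- as.integer(box)
  attr(out, "mask") <- mask
  out
}

sample_cell_spec <- function(geom, canvas, margin) {
  len <- runif(1, geom$length[1], geom$length[2])
  wid <- max(3, len * runif(1, geom$width_ratio[1], geom$width_ratio[2]))
  sep <- sample(names(geom$septum_probs), 1, prob = geom$septum_probs)
  crease <- 0
  if (runif(1) < geom$crease_prob)
    crease <- runif(1, geom$crease_width[1], geom$crease_width[2])
  rad <- len / 2 + 2
  if (any(rad + margin >= canvas - rad - margin))
    return(NULL)   # this draw cannot fit the canvas; caller retries
  center <- c(runif(1, rad + margin, canvas[1] - rad - margin),
              runif(1, rad + margin, canvas[2] - rad - margin))
  cell_spec(center = center, length = len, width = wid,
            orientation = sample_orientation(geom$orientation), septum = sep,
            crease_width = crease,
            intensity = runif(1, geom$intensity[1], geom$intensity[2]))
}

#' Generate one synthetic microscope image with ground truth
#'
#' Places `n_cells` non-overlapping cells of one class on a noisy light
#' background by rejection sampling, then adds Gaussian background noise.
#'
#' @param config a [synth_config()].
#' @param class_name `"longitudinal_division"` or `"other_division"`.
#' @param n_cells how many cells to place (defaults to a draw from
#'   `config$cells_per_image`).
#' @param max_retries placement attempts per cell before giving up.
#' @return list with `image` (numeric matrix in `[0,1]`) and `truth`, a
#'   data.frame with one row per cell: `class_id, row0, col0, row1, col1`
#'   (0-based half-open boxes).
#' @details Sampling uses the R RNG stream; seed it (or call through
#'   [generate_dataset()], which derives per-image seeds from the config
#'   seed) for reproducibility.
#' @export
generate_microscope_image <- function(config, class_name, n_cells = NULL,
                                      max_retries = 200) {
  stopifnot(inherits(config, "synth_config"))
  class_id <- match(class_name, c("longitudinal_division", "other_division")) - 1L
  if (is.na(class_id)) stop("unknown class name: ", class_name)
  geom <- config$class_geometry[[class_name]]
  if (is.null(n_cells)) {
    rng <- config$cells_per_image
    n_cells <- if (rng[1] == rng[2]) rng[1] else
      sample(seq(rng[1], rng[2]), 1)
  }
  canvas <- matrix(config$background, config$canvas[1], config$canvas[2])
  boxes <- matrix(NA_integer_, 0, 4)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      spec <- sample_cell_spec(geom, config$canvas, margin = 2)
      if (is.null(spec)) next
      cand <- render_cell(canvas, spec, background = config$background)
      box <- attr(cand, "box")
      # reject if the padded box intersects any existing cell box
      pad <- 3L
      if (nrow(boxes) > 0) {
        b <- box + c(-pad, -pad, pad, pad)
        hit <- boxes[, 1] < b[3] & b[1] < boxes[, 3] &
               boxes[, 2] < b[4] & b[2] < boxes[, 4]
        if (any(hit)) next
      }
      canvas <- cand
      boxes <- rbind(boxes, box)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("could not place cell %d of %d on a %dx%d canvas ",
                          "after %d retries; reduce cells_per_image or ",
                          "enlarge the canvas"),
                   i, n_cells, config$canvas[1], config$canvas[2], max_retries))
  }
  img <- canvas
  if (config$background_noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, config$background_noise_sd),
                        nrow(img))
  img <- clamp01(img)
  if (config$invert) img <- 1 - img
  truth <- data.frame(class_id = rep(class_id, n_cells),
                      row0 = boxes[, 1], col0 = boxes[, 2],
                      row1 = boxes[, 3], col1 = boxes[, 4])
  attributes(img) <- attributes(img)["dim"]
  list(image = img, truth = truth)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `images_per_class` grayscale PNG microscope images per class into
#' class-named subfolders of `out_dir` (all images of one class in one
#' folder), plus a CSV manifest with one row per planted cell recording its
#' ground-truth bounding box.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame with columns
#'   `path, class_id, src_image, row0, col0, row1, col1`; also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  classes <- c("longitudinal_division", "other_division")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (cl in classes) {
    cdir <- file.path(out_dir, cl)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(config$images_per_class)) {
      res <- with_seed(derive_seed(config$seed, paste0(cl, "#", i)),
                       generate_microscope_image(config, cl))
      fname <- sprintf("%s_%04d.png", cl, i)
      path <- file.path(cdir, fname)
      png::writePNG(res$image, path)
      tr <- res$truth
      tr$path <- path
      tr$src_image <- fname
      rows[[length(rows) + 1L]] <- tr
    }
  }
  manifest <- do.call(rbind, rows)
  manifest <- manifest[, c("path", "class_id", "src_image",
                           "row0", "col0", "row1", "col1")]
  # the CSV stores paths relative to out_dir so regeneration is
  # byte-identical wherever the dataset lands; the returned frame keeps
  # absolute paths for immediate use
  rel <- manifest
  rel$path <- file.path(basename(dirname(manifest$path)),
                        basename(manifest$path))
  write.csv(rel, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a grayscale microscope image
#'
#' Reads a PNG (or single-plane TIFF if the `tiff` package is available)
#' as a numeric matrix in `[0,1]`; RGB images are converted by channel mean.
#'
#' @param path image file.
#' @return numeric matrix, rows = image rows.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}
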