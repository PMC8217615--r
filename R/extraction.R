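#' Otsu's threshold of a grayscale image
#'
#' Maximizes between-class variance over a 256-bin histogram of the image's
#' own intensities.
#'
#' @param image numeric matrix with values in `[0,1]`.
#' @param nbins histogram resolution.
#' @return threshold in `(0,1)`.
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  x <- as.vector(image)
  if (any(!is.finite(x))) stop("image contains non-finite intensities")
  if (max(x) - min(x) < 1e-12)
    stop("image is constant; Otsu thresholding is undefined - ",
         "use a fixed threshold instead")
  h <- tabulate(pmin(floor(x * nbins) + 1L, nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(nbins) - 0.5) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)
  k / nbins
}

#' Binarize a microscope image
#'
#' Converts a grayscale image to black-and-white: foreground ("black
#' pixels") are the pixels darker than the threshold, following the
#' phase-contrast convention of dark cells on a light background. With
#' `invert = TRUE` the lighter pixels become foreground instead.
#'
#' @param image numeric matrix in `[0,1]`.
#' @param threshold `"otsu"` (computed from the image's own histogram) or a
#'   fixed numeric value in `(0,1)`.
#' @param invert flip the foreground convention.
#' @return logical matrix of the same shape; `TRUE` = foreground.
#' @export
binarize <- function(image, threshold = "otsu", invert = FALSE) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  if (any(!is.finite(image))) stop("image contains non-finite intensities")
  thr <- if (identical(threshold, "otsu")) otsu_threshold(image)
         else {
           if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
             stop("fixed threshold must lie in (0,1)")
           threshold
         }
  if (invert) image > thr else image < thr
}

#' Label connected foreground components
#'
#' Assigns each contiguous group of foreground pixels an integer id
#' (each group representing one bacterium). Ids are 1..K in raster-scan
#' order of each component's first pixel; 0 is background.
#'
#' @param binary logical matrix (`TRUE` = foreground).
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return integer matrix of labels with attribute `n_components`.
#' @export
label_components <- function(binary, connectivity = 8L) {
  if (!is.matrix(binary) || !is.logical(binary))
    stop("binary must be a logical matrix")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  label_components_cpp(binary, as.integer(connectivity))
}

#' Tight bounding boxes of labeled components
#'
#' One box per component whose pixel count is at least `min_area`; small
#' areas are ignored according to this a-priori threshold. Boxes are tight
#' (they touch the component's extreme pixels), 0-based and half-open, and
#' are returned in component-id order.
#'
#' @param labeling integer label matrix from [label_components()].
#' @param min_area minimum component area in pixels.
#' @return data.frame `id, row0, col0, row1, col1, area`.
#' @export
bounding_boxes <- function(labeling, min_area = 50L) {
  if (min_area < 0) stop("min_area must be >= 0")
  K <- attr(labeling, "n_components")
  if (is.null(K)) K <- max(0L, max(labeling))
  if (K == 0L)
    return(data.frame(id = integer(), row0 = integer(), col0 = integer(),
                      row1 = integer(), col1 = integer(), area = integer()))
  idx <- which(labeling > 0L, arr.ind = TRUE)
  lab <- labeling[labeling > 0L]
  area <- tabulate(lab, K)
  r0 <- tapply(idx[, 1], lab, min); r1 <- tapply(idx[, 1], lab, max)
  c0 <- tapply(idx[, 2], lab, min); c1 <- tapply(idx[, 2], lab, max)
  out <- data.frame(id = seq_len(K),
                    row0 = as.integer(r0) - 1L, col0 = as.integer(c0) - 1L,
                    row1 = as.integer(r1), col1 = as.integer(c1),
                    area = area)
  out[out$area >= min_area, , drop = FALSE]
}

#' Export cell crops as PNG files
#'
#' Writes one PNG per bounding box containing the original grayscale
#' intensities (not the binary mask) of the padded box, clipped to the image
#' bounds. Filenames encode the source image stem and the box index.
#'
#' @param image numeric matrix (the original intensities).
#' @param boxes data.frame with `row0, col0, row1, col1` (0-based,
#'   half-open).
#' @param out_dir output directory.
#' @param padding pixels of context added on each side before clipping.
#' @param stem filename stem for the crops.
#' @return character vector of written paths.
#' @export
extract_crops <- function(image, boxes, out_dir, padding = 2L,
                          stem = "image") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  H <- nrow(image); W <- ncol(image)
  paths <- character(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    r0 <- max(0L, boxes$row0[i] - padding); r1 <- min(H, boxes$row1[i] + padding)
    c0 <- max(0L, boxes$col0[i] - padding); c1 <- min(W, boxes$col1[i] + padding)
    crop <- image[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
    paths[i] <- file.path(out_dir, sprintf("%s_cell%03d.png", stem, i))
    png::writePNG(crop, paths[i])
  }
  paths
}

#' Extract all cells from a folder of microscope images
#'
#' The full pre-processing chain of the pipeline: each image is binarized,
#' contiguous foreground groups are labeled, small areas are discarded, each
#' surviving group is bounding-boxed, and its crop is exported to PNG.
#'
#' @param in_dir folder of PNG/TIFF microscope images (one class).
#' @param out_dir folder to receive the crops.
#' @param threshold,connectivity,min_area,invert,padding see [binarize()],
#'   [label_components()], [bounding_boxes()], [extract_crops()].
#' @return data.frame `src, path, row0, col0, row1, col1, area`, also
#'   written to `out_dir/boxes.csv`.
#' @export
extract_cells <- function(in_dir, out_dir, threshold = "otsu",
                          connectivity = 8L, min_area = 50L,
                          invert = FALSE, padding = 2L) {
  files <- list.files(in_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0) stop("no images found under ", in_dir)
  rows <- list()
  for (f in files) {
    img <- read_image(f)
    bw <- binarize(img, threshold, invert)
    lab <- label_components(bw, connectivity)
    boxes <- bounding_boxes(lab, min_area)
    stem <- tools::file_path_sans_ext(basename(f))
    paths <- extract_crops(img, boxes, out_dir, padding, stem)
    if (nrow(boxes) > 0)
      rows[[length(rows) + 1L]] <-
        data.frame(src = basename(f), path = paths, boxes[, -1, drop = FALSE],
                   row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(src = character(), path = character(), row0 = integer(),
               col0 = integer(), row1 = integer(), col1 = integer(),
               area = integer())
  write.csv(out, file.path(out_dir, "boxes.csv"), row.names = FALSE)
  out
}
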