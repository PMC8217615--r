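#' Train/validation/test partitioning of one class
#'
#' Holds out `test_frac` of the items for testing, then splits the
#' remainder into validation (`val_frac_of_remainder`) and training. Subset
#' sizes use the ceiling convention on the held-out counts, which with the
#' default fractions reproduces the published per-class subset sizes
#' (e.g. 2,244 items give 1,202 / 301 / 741); sizes depend only on `n`,
#' membership only on the seed.
#'
#' @param items item vector, or a single count `n` (items become `1:n`).
#' @param test_frac fraction held out for testing (default 0.33).
#' @param val_frac_of_remainder fraction of the remainder used for
#'   validation (default 0.2, i.e. an 80/20 train/validation split).
#' @param seed integer seed controlling membership.
#' @return list with elements `train`, `val`, `test` (disjoint, exhaustive).
#' @export
split_class <- function(items, test_frac = 0.33,
                        val_frac_of_remainder = 0.2, seed = 1L) {
  if (test_frac <= 0 || test_frac >= 1 ||
      val_frac_of_remainder <= 0 || val_frac_of_remainder >= 1)
    stop("split fractions must lie in (0,1)")
  if (length(items) == 1 && is.numeric(items)) items <- seq_len(items)
  n <- length(items)
  if (n < 3) stop("need at least 3 items to form three subsets")
  n_test <- as.integer(ceiling(n * test_frac))
  n_val <- as.integer(ceiling((n - n_test) * val_frac_of_remainder))
  n_train <- n - n_test - n_val
  if (min(n_train, n_val, n_test) < 1)
    stop("split produces an empty subset for n = ", n)
  perm <- with_seed(seed, sample.int(n))
  list(train = items[perm[seq_len(n_train)]],
       val = items[perm[n_train + seq_len(n_val)]],
       test = items[perm[n_train + n_val + seq_len(n_test)]])
}

#' Build a dataset manifest from class-named folders
#'
#' Lists every image under the class subfolders of `root` and assigns class
#' ids in lexicographic folder-name order, so `longitudinal_division` is
#' class 0 and `other_division` is class 1. Non-image files are skipped with
#' a warning.
#'
#' @param root directory containing one subfolder per class.
#' @return data.frame `path, class_id, class_name`.
#' @export
build_manifest <- function(root) {
  dirs <- sort(list.dirs(root, recursive = FALSE))
  dirs <- dirs[vapply(dirs, function(d)
    length(list.files(d)) > 0 || TRUE, logical(1))]
  if (length(dirs) < 2) stop("need at least 2 class folders under ", root)
  rows <- list()
  for (k in seq_along(dirs)) {
    files <- list.files(dirs[k], full.names = TRUE)
    keep <- grepl("\\.(png|tif|tiff)$", files, ignore.case = TRUE)
    if (any(!keep))
      warning(sprintf("skipping %d non-image file(s) under %s",
                      sum(!keep), basename(dirs[k])))
    files <- files[keep]
    if (length(files) == 0) stop("class folder is empty: ", dirs[k])
    rows[[k]] <- data.frame(path = files, class_id = k - 1L,
                            class_name = basename(dirs[k]))
  }
  do.call(rbind, rows)
}

#' Assign stratified splits to a manifest
#'
#' Applies [split_class()] independently within each class and adds a
#' `split` column with values `"train"`, `"val"`, `"test"`.
#'
#' @param manifest data.frame from [build_manifest()].
#' @param test_frac,val_frac_of_remainder,seed see [split_class()].
#' @return the manifest with a `split` column.
#' @export
assign_splits <- function(manifest, test_frac = 0.33,
                          val_frac_of_remainder = 0.2, seed = 1L) {
  manifest$split <- NA_character_
  for (cid in sort(unique(manifest$class_id))) {
    idx <- which(manifest$class_id == cid)
    sp <- split_class(idx, test_frac, val_frac_of_remainder,
                      seed = derive_seed(seed, paste0("split", cid)))
    manifest$split[sp$train] <- "train"
    manifest$split[sp$val] <- "val"
    manifest$split[sp$test] <- "test"
  }
  manifest
}

#' Augmentation specification
#'
#' At load time every crop is resized to `resize` pixels (bilinear); in
#' training mode it is then randomly rotated (uniform in
#' `[-rotation, +rotation]` degrees, corners filled with the image median)
#' and randomly flipped horizontally and vertically, then replicated to 3
#' channels and normalized per channel. Evaluation mode applies only
#' resize + normalization so reported metrics are deterministic.
#'
#' @param resize target spatial size (square), default 128.
#' @param rotation maximum absolute rotation in degrees.
#' @param hflip_prob,vflip_prob flip probabilities.
#' @param normalize_mean,normalize_std per-channel constants; defaults are
#'   the ImageNet statistics used when fine-tuning pretrained weights. Use
#'   `c(0.5,0.5,0.5)` for training from scratch.
#' @return object of class `augment_spec`.
#' @export
augment_spec <- function(resize = 128L, rotation = 180,
                         hflip_prob = 0.5, vflip_prob = 0.5,
                         normalize_mean = c(0.485, 0.456, 0.406),
                         normalize_std = c(0.229, 0.224, 0.225)) {
  if (resize < 1) stop("resize must be positive")
  if (any(c(hflip_prob, vflip_prob) < 0 | c(hflip_prob, vflip_prob) > 1))
    stop("flip probabilities must lie in [0,1]")
  structure(list(resize = as.integer(resize), rotation = rotation,
                 hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 normalize_mean = normalize_mean,
                 normalize_std = normalize_std),
            class = "augment_spec")
}

#' Bilinear resize of a grayscale image
#'
#' @param image numeric matrix.
#' @param out_h,out_w target size in pixels.
#' @return numeric matrix `out_h x out_w`.
#' @export
resize_bilinear <- function(image, out_h, out_w) {
  H <- nrow(image); W <- ncol(image)
  if (H == 0 || W == 0) stop("cannot resize a degenerate (0-sized) image")
  sy <- H / out_h; sx <- W / out_w
  yy <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), H - 1)
  xx <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), W - 1)
  y0 <- floor(yy); x0 <- floor(xx)
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- yy - y0; wx <- xx - x0
  a <- image[y0 + 1, x0 + 1, drop = FALSE]; b <- image[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- image[y1 + 1, x0 + 1, drop = FALSE]; d <- image[y1 + 1, x1 + 1, drop = FALSE]
  top <- a + sweep(b - a, 2, wx, "*")
  bot <- c_ + sweep(d - c_, 2, wx, "*")
  top + sweep(bot - top, 1, wy, "*")
}

#' Rotate a grayscale image about its center
#'
#' Inverse-mapped bilinear rotation; pixels sampled outside the source are
#' filled with `fill` (default: the image median, i.e. background).
#'
#' @param image numeric matrix.
#' @param degrees rotation angle (counter-clockwise).
#' @param fill fill value for uncovered corners.
#' @return numeric matrix of the same size.
#' @export
rotate_image <- function(image, degrees, fill = NULL) {
  H <- nrow(image); W <- ncol(image)
  if (is.null(fill)) fill <- median(image)
  th <- degrees * pi / 180
  co <- cos(th); si <- sin(th)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H), times = W) - cy
  gx <- rep(seq_len(W), each = H) - cx
  sy <- co * gy - si * gx + cy
  sx <- si * gy + co * gx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0; wx <- sx - x0
  val <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- rep(fill, length(r))
    v[ok] <- image[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - wy) * (1 - wx) * val(y0, x0) + (1 - wy) * wx * val(y0, x0 + 1) +
       wy * (1 - wx) * val(y0 + 1, x0) + wy * wx * val(y0 + 1, x0 + 1)
  matrix(v, H, W)
}

#' Apply load-time augmentation to one crop
#'
#' @param image grayscale matrix or `H x W x 3` array in `[0,1]`.
#' @param spec an [augment_spec()].
#' @param training apply the random rotation/flips (`TRUE`) or only the
#'   deterministic resize + normalization (`FALSE`).
#' @return `resize x resize x 3` numeric array, normalized per channel.
#' @details Random draws come from the R RNG stream; callers seed it once
#'   per run.
#' @export
augment <- function(image, spec = augment_spec(), training = TRUE) {
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), mean)
  if (nrow(image) == 0 || ncol(image) == 0)
    stop("cannot augment a degenerate (0-sized) image")
  x <- resize_bilinear(image, spec$resize, spec$resize)
  if (training) {
    if (spec$rotation > 0)
      x <- rotate_image(x, runif(1, -spec$rotation, spec$rotation))
    if (runif(1) < spec$hflip_prob) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    if (runif(1) < spec$vflip_prob) x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
  }
  out <- array(0, c(spec$resize, spec$resize, 3))
  for (ch in 1:3)
    out[, , ch] <- (x - spec$normalize_mean[ch]) / spec$normalize_std[ch]
  out
}
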