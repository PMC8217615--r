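# Shared in-code fixtures. Everything is generated at test time; the only
# state kept across files is a session-scoped cache directory so expensive
# artifacts (a small crop dataset, a pretrained checkpoint) are built once.

fixture_dir <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- file.path(tempdir(), "longfission-fixtures")
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    d
  }
})

# A small on-disk crop dataset with splits: 8 microscope images per class,
# 2 cells each -> 16 crops per class.
tiny_crop_manifest <- function() {
  root <- file.path(fixture_dir(), "tinycrops")
  man_path <- file.path(root, "manifest.csv")
  if (!file.exists(man_path)) {
    cfg <- synth_config(images_per_class = 8, cells_per_image = c(2, 2),
                        canvas = c(160, 160), seed = 99)
    generate_dataset(cfg, file.path(root, "images"))
    for (cl in list.dirs(file.path(root, "images"), recursive = FALSE))
      extract_cells(cl, file.path(root, "crops", basename(cl)))
    man <- suppressWarnings(build_manifest(file.path(root, "crops")))
    man <- assign_splits(man, seed = 7)
    write.csv(man, man_path, row.names = FALSE)
  }
  read.csv(man_path)
}

# Independent recursive flood-fill labeling oracle (depth-first, pure R).
floodfill_labels <- function(bin, connectivity = 8) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  k <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!bin[r, c] || lab[r, c] != 0L) next
    k <- k + 1L
    todo <- list(c(r, c))
    lab[r, c] <- k
    while (length(todo)) {
      p <- todo[[length(todo)]]
      todo[[length(todo)]] <- NULL
      for (i in seq_len(nrow(nb))) {
        rr <- p[1] + nb[i, 1]; cc <- p[2] + nb[i, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            bin[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          todo[[length(todo) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Same-partition check up to label renaming.
same_partition <- function(a, b) {
  fa <- as.vector(a); fb <- as.vector(b)
  if (any((fa == 0) != (fb == 0))) return(FALSE)
  on <- fa != 0
  all(!duplicated(unique(cbind(fa[on], fb[on])))[]) &&
    length(unique(fa[on])) == length(unique(fb[on])) &&
    !anyDuplicated(unique(cbind(fa[on], fb[on]))[, 1]) &&
    !anyDuplicated(unique(cbind(fa[on], fb[on]))[, 2])
}

iou_box <- function(a, b) {
  # boxes as c(row0, col0, row1, col1), half-open
  ih <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iw <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ih * iw
  area <- function(x) (x[3] - x[1]) * (x[4] - x[2])
  inter / (area(a) + area(b) - inter)
}
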