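#' Load and validate a run configuration
#'
#' A run configuration is a YAML file with a global `seed`, an `out_dir`,
#' and nested blocks `synth`, `extract`, `split`, `augment`, `model`,
#' `optim` and `train`, each holding only the keys its stage understands
#' (see the package vignette for the full schema). Unknown keys are
#' rejected so typos fail before any stage runs.
#'
#' @param path YAML file, or a named list already parsed.
#' @return validated configuration list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  schema <- list(
    seed = NULL, out_dir = NULL,
    synth = c("images_per_class", "cells_per_image", "canvas", "background",
              "background_noise_sd", "invert"),
    extract = c("threshold", "connectivity", "min_area", "invert", "padding"),
    split = c("test_frac", "val_frac_of_remainder"),
    augment = c("resize", "rotation", "hflip_prob", "vflip_prob",
                "normalize_mean", "normalize_std"),
    model = c("width_mult", "pretrained_path"),
    optim = c("lr", "momentum", "step_period", "gamma"),
    train = c("epochs", "batch_size", "use_kahan"))
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in intersect(names(cfg), names(schema))) {
    if (is.null(schema[[blk]])) next
    extra <- setdiff(names(cfg[[blk]]), schema[[blk]])
    if (length(extra))
      stop("unknown key(s) in '", blk, "': ", paste(extra, collapse = ", "))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "longfission_run"
  structure(cfg, class = "run_config")
}

log_line <- function(run_dir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  cat(msg, "\n", file = file.path(run_dir, "run.log"), append = TRUE)
}

#' Run the classification pipeline end to end
#'
#' Executes the requested stages in pipeline order: `synth` writes
#' synthetic per-class microscope images; `extract` binarizes them and
#' exports one crop per detected cell; `split` builds the stratified
#' train/validation/test manifest; `train` fits the classifier and writes
#' `history.csv` and `best.ckpt`; `evaluate` scores the test split into
#' `confusion.csv` and `metrics.csv`. Each stage reads its predecessor's
#' artifacts from the run directory, so stages can be re-run individually.
#'
#' @param config a [run_config()] (or path to one).
#' @param stages subset of
#'   `c("pretrain","synth","extract","split","train","evaluate")`; the
#'   optional `pretrain` stage self-pretrains a checkpoint on the auxiliary
#'   shape task, which `train` picks up when
#'   `model$pretrained_path: "auto"`.
#' @param verbose print per-epoch training detail.
#' @return the run directory, invisibly; artifacts and `run.log` inside.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "extract", "split", "train",
                                    "evaluate"),
                         verbose = FALSE) {
  all_stages <- c("pretrain", "synth", "extract", "split", "train",
                  "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!inherits(config, "run_config")) config <- run_config(config)
  run_dir <- config$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  img_dir <- file.path(run_dir, "images")
  crop_dir <- file.path(run_dir, "crops")
  manifest_path <- file.path(run_dir, "manifest.csv")
  yaml::write_yaml(unclass(config), file.path(run_dir, "run_config.yaml"))

  if ("pretrain" %in% stages) {
    wm <- if (is.null(config$model$width_mult)) 1 else config$model$width_mult
    log_line(run_dir, "pretrain: auxiliary shape task, width_mult ", wm)
    ck <- pretrain_network(width_mult = wm,
                           seed = derive_seed(seed, "pretrain"),
                           verbose = verbose)
    save_checkpoint(ck, file.path(run_dir, "pretrained.ckpt"))
  }
  if ("synth" %in% stages) {
    sc <- do.call(synth_config,
                  c(config$synth, list(seed = derive_seed(seed, "synth"))))
    log_line(run_dir, "synth: generating ", sc$images_per_class,
             " images per class")
    generate_dataset(sc, img_dir)
  }
  if ("extract" %in% stages) {
    if (!dir.exists(img_dir))
      stop("extract requires the synth stage output; run 'synth' first")
    ex <- config$extract
    log_line(run_dir, "extract: binarize + label + bounding boxes")
    for (cl in list.dirs(img_dir, recursive = FALSE)) {
      do.call(extract_cells,
              c(list(in_dir = cl,
                     out_dir = file.path(crop_dir, basename(cl))), ex))
    }
  }
  if ("split" %in% stages) {
    if (!dir.exists(crop_dir))
      stop("split requires extracted crops; run 'extract' first")
    sp <- config$split
    man <- build_manifest(crop_dir)
    man <- do.call(assign_splits,
                   c(list(manifest = man, seed = derive_seed(seed, "split")),
                     sp))
    write.csv(man, manifest_path, row.names = FALSE)
    log_line(run_dir, "split: ", nrow(man), " crops -> ",
             paste(names(table(man$split)), table(man$split),
                   sep = "=", collapse = ", "))
  }
  if ("train" %in% stages) {
    if (!file.exists(manifest_path))
      stop("train requires the split manifest; run 'split' first")
    man <- read.csv(manifest_path)
    tc <- train_config(seed = derive_seed(seed, "train"))
    for (k in intersect(names(config$train), c("epochs", "batch_size",
                                               "use_kahan")))
      tc[[k]] <- config$train[[k]]
    map <- c(lr = "lr", momentum = "momentum", step_period = "lr_period",
             gamma = "lr_gamma")
    for (k in intersect(names(config$optim), names(map)))
      tc[[map[[k]]]] <- config$optim[[k]]
    wm <- if (is.null(config$model$width_mult)) 1 else config$model$width_mult
    pre <- config$model$pretrained_path
    if (identical(pre, "auto")) {
      pre <- file.path(run_dir, "pretrained.ckpt")
      if (!file.exists(pre))
        stop("model$pretrained_path is 'auto' but no pretrained checkpoint ",
             "exists; run the 'pretrain' stage first")
    }
    aug <- if (is.null(config$augment)) NULL else
      do.call(augment_spec, config$augment)
    log_line(run_dir, "train: ", tc$epochs, " epochs, batch ",
             tc$batch_size, ", width_mult ", wm,
             if (!is.null(pre)) ", pretrained" else ", random init")
    fit <- fission_train(man, tc, width_mult = wm, pretrained = pre,
                         spec = aug, verbose = verbose)
    write.csv(fit$history, file.path(run_dir, "history.csv"),
              row.names = FALSE)
    save_checkpoint(fit$network, file.path(run_dir, "best.ckpt"))
    saveRDS(fit, file.path(run_dir, "fit.rds"))
    log_line(run_dir, sprintf("train: best validation accuracy %.4f%% at epoch %d",
                              fit$best_val_accuracy, fit$best_epoch))
  }
  if ("evaluate" %in% stages) {
    fit_path <- file.path(run_dir, "fit.rds")
    if (!file.exists(fit_path) || !file.exists(manifest_path))
      stop("evaluate requires a trained checkpoint; run 'train' first")
    fit <- readRDS(fit_path)
    man <- read.csv(manifest_path)
    rep <- evaluate_fit(fit, man, "test")
    write_metrics(rep, run_dir)
    log_line(run_dir, sprintf("evaluate: test accuracy %.4f%%", rep$accuracy))
  }
  manifest <- list(seed = seed,
                   config_md5 = unname(tools::md5sum(
                     file.path(run_dir, "run_config.yaml"))),
                   stages = stages,
                   artifacts = list.files(run_dir))
  yaml::write_yaml(manifest, file.path(run_dir, "run_manifest.yaml"))
  invisible(run_dir)
}
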