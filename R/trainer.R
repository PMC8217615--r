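#' Training configuration
#'
#' Defaults follow the study setup: 25 epochs, batches of 16 images,
#' learning rate 0.001, momentum 0.9, learning-rate decay period 7 epochs
#' with multiplicative factor 0.1.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size images per weight update.
#' @param lr initial learning rate.
#' @param momentum momentum factor in `[0,1)`.
#' @param lr_period,lr_gamma step decay schedule (see [lr_schedule()]).
#' @param seed integer seed; all run randomness (shuffling, augmentation,
#'   initialization) flows from it.
#' @param use_kahan accumulate epoch-level loss sums with the compensated
#'   accumulator.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 25L, batch_size = 16L, lr = 0.001,
                         momentum = 0.9, lr_period = 7L, lr_gamma = 0.1,
                         seed = 1L, use_kahan = TRUE) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, lr_period = as.integer(lr_period),
                 lr_gamma = lr_gamma, seed = as.integer(seed),
                 use_kahan = isTRUE(use_kahan)),
            class = "train_config")
}

#' Minibatch iterator for one epoch
#'
#' Partitions `1:n` into randomly ordered batches without replacement, so
#' an epoch completes having chosen every item exactly once (the final
#' batch may be smaller). The shuffle draws from the current RNG stream, so
#' each epoch reshuffles.
#'
#' @param n number of items in the split.
#' @param batch_size items per batch; if larger than `n`, a single batch of
#'   all items is returned with a warning.
#' @return list of integer index vectors.
#' @export
minibatch_iter <- function(n, batch_size) {
  if (n < 1) stop("split is empty")
  if (batch_size > n) {
    warning("batch_size exceeds the number of items; using one batch")
    batch_size <- n
  }
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}

acc_add <- function(acc, x, use_kahan) {
  if (use_kahan) kahan_add(acc, x) else list(s = acc$s + sum(x), r = 0)
}

deep_copy <- function(x) unserialize(serialize(x, NULL))

zero_like <- function(x) {
  if (is.list(x)) {
    x[] <- lapply(x, zero_like)
    x
  } else if (is.numeric(x)) x * 0 else x
}

## Forward a list of pre-transformed (H,W,3) arrays in evaluation batches.
eval_pass <- function(net, arrs, labels, config, engine = "cpp") {
  n <- length(arrs)
  loss_acc <- kahan_new()
  preds <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + config$batch_size - 1L, n)
    x <- batch_from_arrays(arrs[i:j])
    bd <- attr(x, "bdim")
    scores <- if (engine == "cpp")
      cpp_net_eval(net, x, bd[2], bd[3], bd[1])
    else net_forward(net, x, training = FALSE, with_cache = FALSE)$scores
    ls <- softmax_xent(scores, labels[i:j])
    loss_acc <- acc_add(loss_acc, ls$loss * (j - i + 1L), config$use_kahan)
    preds[i:j] <- max.col(scores, ties.method = "first") - 1L
    i <- j + 1L
  }
  acc <- if (all(c(preds, labels) %in% c(0, 1)))
    accuracy(confusion(preds, labels)) else 100 * mean(preds == labels)
  list(accuracy = acc, loss = kahan_value(loss_acc) / n, preds = preds)
}

## Core loop shared by fission_train() and pretrain_network(). Images are
## grayscale matrices already resized to spec$resize.
train_network <- function(net, train_imgs, train_labels, val_imgs,
                          val_labels, config, spec, verbose = FALSE,
                          engine = "cpp") {
  n <- length(train_imgs)
  sched <- lr_schedule(config$lr_period, config$lr_gamma)
  # the cpp engine updates parameters in place: detach from any structure
  # the caller may share (e.g. a pretrained checkpoint)
  net <- deep_copy(net)
  vel <- if (engine == "cpp") zero_like(net) else NULL
  # validation transforms are deterministic: compute them once
  val_arrs <- lapply(val_imgs, augment, spec = spec, training = FALSE)
  best <- list(accuracy = -Inf, epoch = NA_integer_, net = NULL)
  hist <- vector("list", config$epochs)
  for (e in seq_len(config$epochs) - 1L) {
    alpha <- lr_at(sched, e, config$lr)
    batches <- minibatch_iter(n, config$batch_size)
    loss_acc <- kahan_new()
    ep_preds <- integer(n); ep_labels <- integer(n); pos <- 1L
    for (bidx in batches) {
      arrs <- lapply(train_imgs[bidx], augment, spec = spec, training = TRUE)
      x <- batch_from_arrays(arrs)
      k <- length(bidx)
      if (engine == "cpp") {
        bd <- attr(x, "bdim")
        res <- cpp_train_batch(net, vel, x, as.integer(train_labels[bidx]),
                               bd[2], bd[3], bd[1], alpha, config$momentum)
        batch_loss <- res$loss
        batch_preds <- res$preds
      } else {
        fwd <- net_forward(net, x, training = TRUE, with_cache = TRUE)
        net <- fwd$net
        ls <- softmax_xent(fwd$scores, train_labels[bidx])
        if (!is.finite(ls$loss))
          stop(sprintf("non-finite training loss at epoch %d (lr %g)",
                       e, alpha))
        batch_loss <- ls$loss
        batch_preds <- max.col(fwd$scores, ties.method = "first") - 1L
        grads <- net_backward(net, fwd$cache, ls$dscores)
        upd <- sgd_update_tree(net, vel, grads, alpha, config$momentum)
        net <- upd$params; vel <- upd$vel
      }
      ep_preds[pos:(pos + k - 1L)] <- batch_preds
      ep_labels[pos:(pos + k - 1L)] <- train_labels[bidx]
      pos <- pos + k
      loss_acc <- acc_add(loss_acc, batch_loss * k, config$use_kahan)
    }
    tr_acc <- if (all(c(ep_preds, ep_labels) %in% c(0, 1)))
      accuracy(confusion(ep_preds, ep_labels)) else
      100 * mean(ep_preds == ep_labels)
    val <- eval_pass(net, val_arrs, val_labels, config, engine)
    hist[[e + 1L]] <- data.frame(
      epoch = e, lr = alpha,
      train_acc = tr_acc, train_loss = kahan_value(loss_acc) / n,
      val_acc = val$accuracy, val_loss = val$loss)
    if (val$accuracy > best$accuracy)
      best <- list(accuracy = val$accuracy, epoch = e, net = deep_copy(net))
    if (verbose)
      message(sprintf(
        "epoch %2d  lr %.2g  train acc %6.2f%%  loss %.4f  val acc %6.2f%%  loss %.4f",
        e, alpha, tr_acc, kahan_value(loss_acc) / n, val$accuracy, val$loss))
  }
  list(history = do.call(rbind, hist), best = best, final_net = net)
}

load_gray_resized <- function(paths, size) {
  lapply(paths, function(p) resize_bilinear(read_image(p), size, size))
}

#' Train the longitudinal-fission classifier
#'
#' The package's central fitting function: trains a (width-scalable)
#' ResNet-18 on single-cell crops with minibatch SGD with momentum, step
#' learning-rate decay, load-time augmentation on the training split, and
#' deterministic transforms for validation. The returned fit keeps the
#' weights of the epoch with the best validation accuracy (earliest epoch
#' on ties), the standard checkpoint convention when a single best
#' validation accuracy is reported.
#'
#' @param manifest data.frame with columns `path`, `class_id` and `split`
#'   (values `"train"`, `"val"`, `"test"`), e.g. from [build_manifest()] +
#'   [assign_splits()].
#' @param config a [train_config()].
#' @param width_mult network width multiplier (1 = full ResNet-18).
#' @param pretrained `NULL` for random initialization, or a checkpoint
#'   (path or `fission_net`, e.g. from [pretrain_network()]) whose non-head
#'   layers initialize the network; all layers are then fine-tuned.
#' @param spec an [augment_spec()]; by default ImageNet normalization
#'   constants are used when fine-tuning a pretrained checkpoint and
#'   0.5/0.5 otherwise.
#' @param verbose print one line per epoch.
#' @return object of class `fission_fit`; see [predict.fission_fit()],
#'   [summary.fission_fit()], [plot.fission_fit()].
#' @export
fission_train <- function(manifest, config = train_config(),
                          width_mult = 1, pretrained = NULL, spec = NULL,
                          verbose = FALSE) {
  stopifnot(all(c("path", "class_id", "split") %in% names(manifest)))
  if (is.null(spec)) {
    spec <- if (is.null(pretrained) || isFALSE(pretrained)) {
      augment_spec(normalize_mean = rep(0.5, 3), normalize_std = rep(0.5, 3))
    } else {
      ck <- if (is.character(pretrained)) load_checkpoint(pretrained)
            else pretrained
      if (!is.null(ck$norm))
        augment_spec(normalize_mean = ck$norm$mean,
                     normalize_std = ck$norm$std)
      else augment_spec()   # ImageNet statistics for external checkpoints
    }
  }
  tr <- manifest[manifest$split == "train", ]
  va <- manifest[manifest$split == "val", ]
  if (nrow(tr) == 0 || nrow(va) == 0)
    stop("train and validation splits must both be non-empty")
  res <- with_seed(config$seed, {
    net <- build_network(width_mult, num_classes = 2L)
    if (!is.null(pretrained) && !isFALSE(pretrained))
      net <- load_pretrained(net, pretrained, num_classes = 2L)
    train_imgs <- load_gray_resized(tr$path, spec$resize)
    val_imgs <- load_gray_resized(va$path, spec$resize)
    train_network(net, train_imgs, tr$class_id, val_imgs, va$class_id,
                  config, spec, verbose)
  })
  structure(list(network = res$best$net, final_network = res$final_net,
                 history = res$history,
                 best_val_accuracy = res$best$accuracy,
                 best_epoch = res$best$epoch,
                 config = config, augment = spec,
                 width_mult = width_mult,
                 pretrained = !is.null(pretrained) && !isFALSE(pretrained),
                 classes = c("longitudinal_division", "other_division"),
                 n_train = nrow(tr), n_val = nrow(va),
                 call = match.call()),
            class = "fission_fit")
}

#' Self-pretrain a network on an auxiliary synthetic shape task
#'
#' Stands in for an ImageNet-pretrained checkpoint: trains the same
#' backbone on a four-class synthetic rod-morphology task (narrow/wide
#' crossed with septum presence, rendered at higher noise) so the
#' convolutional layers learn oriented-edge and septum features that
#' transfer to the binary fission task. The returned checkpoint has a
#' four-way head, which [load_pretrained()] replaces during fine-tuning.
#'
#' @param width_mult backbone width multiplier (must match the fine-tuning
#'   network).
#' @param images_per_class auxiliary images per class.
#' @param epochs pretraining epochs.
#' @param lr,lr_period,lr_gamma pretraining optimizer settings; defaults
#'   favor a larger rate with gentler decay than fine-tuning, appropriate
#'   for training from scratch.
#' @param resolution pretraining input size in pixels. Auxiliary images are
#'   rendered and trained at 64 px by default: all layers are convolutional
#'   up to the global pooling, so the learned filters apply unchanged to
#'   128-px fine-tuning inputs at a quarter of the cost.
#' @param seed integer seed.
#' @param verbose print one line per epoch.
#' @return a `fission_net` checkpoint with a 4-class head and a `norm`
#'   field recording the normalization constants it was trained with.
#' @export
pretrain_network <- function(width_mult = 1, images_per_class = 250L,
                             epochs = 24L, lr = 0.003, lr_period = 10L,
                             lr_gamma = 0.3, resolution = 64L, seed = 1L,
                             verbose = FALSE) {
  specs <- list(
    list(ratio = c(0.25, 0.42), septum = "none"),
    list(ratio = c(0.25, 0.42), septum = "transverse"),
    list(ratio = c(0.58, 0.75), septum = "longitudinal"),
    list(ratio = c(0.58, 0.75), septum = "none"))
  aug <- augment_spec(resize = resolution,
                      normalize_mean = rep(0.5, 3),
                      normalize_std = rep(0.5, 3))
  cfg <- train_config(epochs = epochs, batch_size = 16L, lr = lr,
                      momentum = 0.9, lr_period = lr_period,
                      lr_gamma = lr_gamma, seed = seed)
  with_seed(derive_seed(seed, "pretrain"), {
    imgs <- list(); labels <- integer()
    for (k in seq_along(specs)) {
      g <- specs[[k]]
      for (i in seq_len(images_per_class)) {
        len <- runif(1, 26, 50)
        wid <- max(3, len * runif(1, g$ratio[1], g$ratio[2]))
        bg <- runif(1, 0.8, 0.92)
        canvas <- matrix(bg, 72, 72)
        sp <- cell_spec(center = c(36, 36) + runif(2, -2, 2), length = len,
                        width = wid,
                        orientation = sample_orientation(
                          list(c(15, 75), c(105, 165))),
                        septum = g$septum,
                        intensity = runif(1, 0.15, 0.3))
        img <- render_cell(canvas, sp)
        img <- clamp01(img + matrix(rnorm(length(img), 0, 0.05), 72))
        # frame like the pipeline's crops: padded tight box, then a square
        # resize (so pretraining sees the same stretch statistics)
        box <- attr(render_cell(canvas, sp), "box")
        r0 <- max(0, box[1] - 2); r1 <- min(72, box[3] + 2)
        c0 <- max(0, box[2] - 2); c1 <- min(72, box[4] + 2)
        crop <- img[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
        imgs[[length(imgs) + 1L]] <- resize_bilinear(crop, resolution,
                                                     resolution)
        labels <- c(labels, k - 1L)
      }
    }
    n <- length(imgs)
    hold <- sample.int(n, max(8L, round(0.1 * n)))
    net <- build_network(width_mult, num_classes = 4L)
    res <- train_network(net, imgs[-hold], labels[-hold], imgs[hold],
                         labels[hold], cfg, aug, verbose)
    ck <- res$best$net
    ck$norm <- list(mean = aug$normalize_mean, std = aug$normalize_std)
    ck
  })
}

transform_eval <- function(imgs, spec) {
  lapply(imgs, function(m)
    augment(resize_bilinear(m, spec$resize, spec$resize), spec,
            training = FALSE))
}

#' Predict classes for new cell images
#'
#' Applies the deterministic evaluation transform (resize + normalization)
#' and the fitted network. The predicted class is the index of the maximal
#' score; exact ties resolve to the lower class index.
#'
#' @param object a [fission_train()] fit.
#' @param newdata image paths (or a directory of images), a manifest
#'   data.frame with a `path` column, or a list of grayscale matrices.
#' @param type `"class"` for a data.frame of predictions and class
#'   probabilities, `"prob"` for the probability matrix only.
#' @param ... unused.
#' @return data.frame `path, pred, score0, score1` (softmax scores), or the
#'   score matrix for `type = "prob"`.
#' @export
predict.fission_fit <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  paths <- NULL
  if (is.character(newdata) && length(newdata) == 1 && dir.exists(newdata))
    newdata <- list.files(newdata, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE)
  if (is.data.frame(newdata)) newdata <- newdata$path
  if (is.character(newdata)) {
    paths <- newdata
    imgs <- lapply(newdata, read_image)
  } else imgs <- newdata
  if (length(imgs) == 0) stop("no images to predict")
  arrs <- transform_eval(imgs, object$augment)
  n <- length(arrs)
  scores <- matrix(NA_real_, n, 2)
  i <- 1L
  while (i <= n) {
    j <- min(i + object$config$batch_size - 1L, n)
    x <- batch_from_arrays(arrs[i:j])
    bd <- attr(x, "bdim")
    sc <- cpp_net_eval(object$network, x, bd[2], bd[3], bd[1])
    e <- exp(sc - apply(sc, 1, max))
    scores[i:j, ] <- e / rowSums(e)
    i <- j + 1L
  }
  if (type == "prob") return(scores)
  data.frame(path = if (is.null(paths)) NA_character_ else paths,
             pred = max.col(scores, ties.method = "first") - 1L,
             score0 = scores[, 1], score1 = scores[, 2])
}

#' Evaluate a fit on the test split
#'
#' @param fit a `fission_fit`.
#' @param manifest manifest with `path`, `class_id`, `split` columns.
#' @param split which split to evaluate (default `"test"`).
#' @return a [metrics_report()] with an extra `loss` element.
#' @export
evaluate_fit <- function(fit, manifest, split = "test") {
  te <- manifest[manifest$split == split, ]
  if (nrow(te) == 0) stop("no items in split '", split, "'")
  imgs <- lapply(te$path, read_image)
  arrs <- transform_eval(imgs, fit$augment)
  ev <- eval_pass(fit$network, arrs, te$class_id, fit$config)
  rep <- metrics_report(confusion(ev$preds, te$class_id))
  rep$loss <- ev$loss
  rep
}

#' @export
print.fission_fit <- function(x, ...) {
  cat(sprintf("Longitudinal-fission classifier (%s ResNet-18, width %.3g)\n",
              if (x$pretrained) "fine-tuned" else "from-scratch",
              x$width_mult))
  cat(sprintf("  trained %d epochs on %d images (validation: %d)\n",
              nrow(x$history), x$n_train, x$n_val))
  cat(sprintf("  best validation accuracy: %.4f%% at epoch %d\n",
              x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' @export
summary.fission_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.fission_fit <- function(object, ...) {
  out <- list()
  grab <- function(x, prefix) {
    if (!is.list(x)) return()
    if (!is.null(x$type) && x$type == "conv") out[[paste0(prefix, ".W")]] <<- x$W
    else if (!is.null(x$type) && x$type == "bn") {
      out[[paste0(prefix, ".gamma")]] <<- x$gamma
      out[[paste0(prefix, ".beta")]] <<- x$beta
    } else {
      nms <- names(x)
      for (i in seq_along(x)) {
        tag <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        if (is.list(x[[i]])) grab(x[[i]], paste0(prefix, ".", tag))
      }
    }
  }
  grab(object$network$stem, "stem")
  grab(object$network$stages, "stage")
  out[["fc.W"]] <- object$network$fc$W
  out[["fc.b"]] <- object$network$fc$b
  out
}

#' Plot training history
#'
#' Accuracy and loss curves for the training and validation sets against
#' the epoch counter.
#'
#' @param x a `fission_fit`.
#' @param ... passed to [matplot()].
#' @export
plot.fission_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "accuracy (%)",
                    main = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss",
                    main = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(h)
}
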