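test_that("minibatch_iter partitions an epoch without replacement", {
  set.seed(1)
  b <- minibatch_iter(100, 16)
  expect_identical(length(b), 7L)
  expect_identical(unname(lengths(b)), c(rep(16L, 6), 4L))
  expect_identical(sort(unlist(b, use.names = FALSE)), 1:100)
  # determinism under a fixed seed
  set.seed(42); b1 <- minibatch_iter(50, 8)
  set.seed(42); b2 <- minibatch_iter(50, 8)
  expect_identical(b1, b2)
  # oversized batch collapses to one batch with a warning
  expect_warning(b3 <- minibatch_iter(5, 16), "batch_size")
  expect_identical(lengths(b3), c(`1` = 5L))
})

test_that("one epoch on a small synthetic set yields a usable fit", {
  man <- tiny_crop_manifest()
  spec <- augment_spec(resize = 48, normalize_mean = rep(0.5, 3),
                       normalize_std = rep(0.5, 3))
  fit <- fission_train(man, train_config(epochs = 1, batch_size = 8,
                                         seed = 3),
                       width_mult = 0.1, spec = spec)
  expect_s3_class(fit, "fission_fit")
  expect_identical(nrow(fit$history), 1L)
  expect_identical(fit$best_epoch, 0L)
  expect_true(all(c("epoch", "lr", "train_acc", "train_loss", "val_acc",
                    "val_loss") %in% names(fit$history)))
  expect_true(all(fit$history$train_acc >= 0 & fit$history$train_acc <= 100))
  # the checkpoint round-trips
  p <- tempfile(fileext = ".ckpt")
  save_checkpoint(fit$network, p)
  expect_identical(load_checkpoint(p)$fc$W, fit$network$fc$W)
  # methods run
  expect_output(print(fit), "classifier")
  expect_silent(co <- coef(fit))
  expect_true("fc.W" %in% names(co))
})

test_that("the validation pass never changes the weights", {
  man <- tiny_crop_manifest()
  net <- build_network(0.1, seed = 2)
  va <- man[man$split == "val", ]
  spec <- augment_spec(resize = 48, normalize_mean = rep(0.5, 3),
                       normalize_std = rep(0.5, 3))
  imgs <- lapply(va$path, read_image)
  arrs <- lapply(imgs, function(m) augment(m, spec, training = FALSE))
  before <- serialize(net, NULL)
  ev <- longfission:::eval_pass(net, arrs, va$class_id,
                                train_config(batch_size = 4))
  expect_identical(serialize(net, NULL), before)
  expect_identical(length(ev$preds), nrow(va))
})

test_that("training histories use the shared metric definitions", {
  man <- tiny_crop_manifest()
  spec <- augment_spec(resize = 48, normalize_mean = rep(0.5, 3),
                       normalize_std = rep(0.5, 3))
  fit <- fission_train(man, train_config(epochs = 2, batch_size = 8,
                                         seed = 4),
                       width_mult = 0.1, spec = spec)
  # best accuracy is the max of the history, at its earliest epoch
  expect_equal(fit$best_val_accuracy, max(fit$history$val_acc))
  expect_identical(fit$best_epoch,
                   fit$history$epoch[which.max(fit$history$val_acc)])
  # lr column follows the configured schedule
  expect_equal(fit$history$lr,
               vapply(fit$history$epoch, lr_at, numeric(1),
                      schedule = lr_schedule(fit$config$lr_period,
                                             fit$config$lr_gamma),
                      alpha = fit$config$lr))
})

test_that("training is deterministic given the config seed", {
  man <- tiny_crop_manifest()
  spec <- augment_spec(resize = 32, normalize_mean = rep(0.5, 3),
                       normalize_std = rep(0.5, 3))
  cfg <- train_config(epochs = 1, batch_size = 8, seed = 11)
  f1 <- fission_train(man, cfg, width_mult = 0.1, spec = spec)
  f2 <- fission_train(man, cfg, width_mult = 0.1, spec = spec)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$fc$W, f2$network$fc$W)
})

test_that("predict returns ordered predictions with the documented tie-break", {
  man <- tiny_crop_manifest()
  spec <- augment_spec(resize = 32, normalize_mean = rep(0.5, 3),
                       normalize_std = rep(0.5, 3))
  fit <- fission_train(man, train_config(epochs = 1, batch_size = 8,
                                         seed = 5),
                       width_mult = 0.1, spec = spec)
  te <- man[man$split == "test", ]
  pr <- predict(fit, te)
  expect_identical(nrow(pr), nrow(te))
  expect_identical(pr$path, te$path)
  expect_true(all(pr$pred %in% c(0L, 1L)))
  expect_equal(pr$score0 + pr$score1, rep(1, nrow(pr)))
  # exact tie in scores resolves to the lower class index
  fit0 <- fit
  fit0$network$fc$W[] <- 0
  fit0$network$fc$b[] <- c(0.3, 0.3)
  pr0 <- predict(fit0, te[1:3, ])
  expect_identical(pr0$pred, rep(0L, 3))
})

test_that("non-finite losses abort with diagnostics", {
  man <- tiny_crop_manifest()
  spec <- augment_spec(resize = 32, normalize_mean = rep(0.5, 3),
                       normalize_std = rep(0.5, 3))
  # a corrupted head makes the loss NaN; the engine must refuse to update
  bad <- build_network(0.1, num_classes = 2, seed = 6)
  bad$fc$b[1] <- NaN
  imgs <- lapply(man$path[1:4], read_image)
  arrs <- lapply(imgs, function(m) augment(m, spec, training = FALSE))
  x <- longfission:::batch_from_arrays(arrs)
  expect_error(
    longfission:::cpp_train_batch(bad, longfission:::zero_like(bad), x,
                                  c(0L, 1L, 0L, 1L), 32L, 32L, 4L,
                                  0.001, 0.9),
    "non-finite")
  # the reference engine enforces the same contract
  expect_error(longfission:::sgd_update_tree(bad, NULL,
                                             list(fc = list(b = c(NaN, 0))),
                                             0.1, 0.9),
               "non-finite")
})
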