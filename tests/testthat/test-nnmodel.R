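# brute-force valid cross-correlation oracle
conv_oracle <- function(img, ker, stride = 1) {
  oh <- (nrow(img) - nrow(ker)) %/% stride + 1
  ow <- (ncol(img) - ncol(ker)) %/% stride + 1
  out <- matrix(NA_real_, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    rs <- (i - 1) * stride + seq_len(nrow(ker))
    cs <- (j - 1) * stride + seq_len(ncol(ker))
    out[i, j] <- sum(img[rs, cs] * ker)
  }
  out
}

test_that("a 4x4 image with a 2x2 kernel at stride 1 gives a 3x3 feature map", {
  # first rows chosen so the first receptive fields are (0,1;0,1),
  # (1,0;1,1) and (0,1;1,0)
  img <- matrix(c(0, 0, 0, 0,
                  1, 1, 1, 1,
                  0, 1, 0, 1,
                  1, 0, 1, 0), 4, 4)
  ker <- matrix(c(1, 3, 2, 4), 2, 2)  # (a,b;c,d) = (1,2;3,4)
  fm <- convolve2d_valid(img, ker)
  expect_identical(dim(fm), c(3L, 3L))
  # inner products instantiating b+d, a+c+d, b+c with (1,2,3,4)
  expect_identical(fm[1, 1], 2 + 4)      # b + d = 6
  expect_identical(fm[1, 2], 1 + 3 + 4)  # a + c + d = 8
  expect_identical(fm[1, 3], 2 + 3)      # b + c = 5
  expect_identical(fm[2, 1], 2 + 4)      # next row starts again with b + d
  expect_identical(fm, conv_oracle(img, ker))
})

test_that("convolution agrees with the brute-force oracle on random inputs", {
  set.seed(11)
  for (stride in 1:2) {
    img <- matrix(sample(-5:5, 64, TRUE), 8, 8)
    ker <- matrix(sample(-3:3, 9, TRUE), 3, 3)
    expect_identical(convolve2d_valid(img, ker, stride),
                     conv_oracle(img, ker, stride))
  }
  img <- matrix(rnorm(36), 6, 6)
  expect_identical(convolve2d_valid(img, matrix(1, 1, 1)), img)
  expect_error(convolve2d_valid(matrix(0, 2, 2), matrix(0, 3, 3)), "larger")
})

test_that("a zero-weight residual block is the identity map", {
  set.seed(2)
  blk <- make_residual_block(4, 4, 1)
  blk$conv1$W[] <- 0; blk$conv2$W[] <- 0
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  y <- residual_block_forward(x, blk, training = TRUE)
  expect_equal(y, x, tolerance = 1e-6)
})

test_that("the block output minus input equals the inner path alone", {
  set.seed(3)
  blk <- make_residual_block(3, 3, 1)
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  y <- residual_block_forward(x, blk, training = TRUE)
  # evaluate f(x, w) independently, layer by layer
  xb <- longfission:::batch_from_arrays(list(x))
  c1 <- longfission:::conv_fwd(blk$conv1, xb, c(1L, 5L, 5L))
  b1 <- longfission:::bn_fwd(blk$bn1, c1$y, TRUE)
  r1 <- pmax(b1$y, 0)
  c2 <- longfission:::conv_fwd(blk$conv2, r1, c1$bdim)
  b2 <- longfission:::bn_fwd(blk$bn2, c2$y, TRUE)
  f <- array(b2$y, c(5, 5, 3))
  expect_equal(y - x, f, tolerance = 1e-10)

  # constant residual: adding c elementwise
  expect_equal(residual_block_forward(x, blk, training = TRUE) - x, f)
})

test_that("network topology: head size, width monotonicity, finite scores", {
  net <- build_network(width_mult = 0.25, num_classes = 2, seed = 1)
  expect_identical(ncol(net$fc$W), 2L)
  small <- build_network(width_mult = 0.1, seed = 1)
  expect_lt(count_parameters(small), count_parameters(net))
  x <- array(rnorm(128 * 128 * 3), c(128, 128, 3))
  xb <- longfission:::batch_from_arrays(list(x))
  sc <- longfission:::cpp_net_eval(net, xb, 128L, 128L, 1L)
  expect_identical(dim(sc), c(1L, 2L))
  expect_true(all(is.finite(sc)))
  expect_error(build_network(0), "width_mult")
})

test_that("the C++ engine matches the R reference implementation", {
  set.seed(5)
  net <- build_network(0.1, seed = 9)
  arrs <- lapply(1:3, function(i) array(rnorm(64 * 64 * 3), c(64, 64, 3)))
  xb <- longfission:::batch_from_arrays(arrs)
  r <- longfission:::net_forward(net, xb, training = FALSE)$scores
  cpp <- longfission:::cpp_net_eval(net, xb, 64L, 64L, 3L)
  expect_equal(r, cpp, tolerance = 1e-4, ignore_attr = TRUE)

  # one training step: same loss and same parameter updates
  netA <- longfission:::deep_copy(net)
  velA <- longfission:::zero_like(netA)
  lab <- c(0L, 1L, 0L)
  res <- longfission:::cpp_train_batch(netA, velA, xb, lab, 64L, 64L, 3L,
                                       0.01, 0.9)
  fwd <- longfission:::net_forward(net, xb, training = TRUE,
                                   with_cache = TRUE)
  ls <- longfission:::softmax_xent(fwd$scores, lab)
  expect_equal(res$loss, ls$loss, tolerance = 1e-5)
  g <- longfission:::net_backward(fwd$net, fwd$cache, ls$dscores)
  u <- longfission:::sgd_update_tree(fwd$net, NULL, g, 0.01, 0.9)
  expect_equal(netA$fc$W, u$params$fc$W, tolerance = 1e-5)
  expect_equal(netA$stem$conv$W, u$params$stem$conv$W, tolerance = 1e-4)
})

test_that("backward gradients match finite differences on smooth layers", {
  set.seed(7)
  lay <- longfission:::new_conv(2, 3, 3, 2)
  x <- matrix(rnorm(2 * 49 * 2), 2 * 49, 2)
  f <- longfission:::conv_fwd(lay, x, c(2L, 7L, 7L))
  bw <- longfission:::conv_bwd(lay, f$cache, f$y)  # d(sum y^2/2)/dW
  for (idx in c(1, 11, 29)) {
    l2 <- lay; l2$W[idx] <- l2$W[idx] + 1e-6
    num <- (sum(longfission:::conv_fwd(l2, x, c(2L, 7L, 7L))$y^2) / 2 -
              sum(f$y^2) / 2) / 1e-6
    expect_equal(num, bw$grads$W[idx], tolerance = 1e-3)
  }
})

test_that("load_pretrained transfers the backbone and rebuilds the head", {
  ck <- build_network(0.1, num_classes = 4, seed = 1)
  net <- build_network(0.1, num_classes = 2, seed = 2)
  out <- load_pretrained(net, ck, num_classes = 2, seed = 3)
  expect_identical(out$stem$conv$W, ck$stem$conv$W)
  expect_identical(out$stages[[3]][[2]]$conv2$W,
                   ck$stages[[3]][[2]]$conv2$W)
  expect_identical(ncol(out$fc$W), 2L)
  expect_false(isTRUE(all.equal(out$fc$W, net$fc$W)))

  # round-trip through a checkpoint file
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(ck, path)
  out2 <- load_pretrained(net, path, num_classes = 2, seed = 3)
  expect_identical(out2$stem$conv$W, ck$stem$conv$W)

  # topology mismatch errors name the offending layers
  wrong <- build_network(0.2, num_classes = 4, seed = 1)
  expect_error(load_pretrained(net, wrong, 2), "stem")
})

test_that("forward pass is deterministic given weights and input", {
  net <- build_network(0.1, seed = 3)
  xb <- longfission:::batch_from_arrays(
    list(array(rnorm(64 * 64 * 3), c(64, 64, 3))))
  a <- longfission:::cpp_net_eval(net, xb, 64L, 64L, 1L)
  b <- longfission:::cpp_net_eval(net, xb, 64L, 64L, 1L)
  expect_identical(a, b)
})
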