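#' Valid 2-D convolution (cross-correlation) of an image with a kernel
#'
#' Sweeps the kernel over the image left to right, top to bottom at a fixed
#' stride; each output pixel is the inner product of the kernel with the
#' receptive region under it. No kernel flip is applied (the convention of
#' convolutional network layers), and no padding: the output feature map has
#' spatial size `floor((input - kernel)/stride) + 1` per axis.
#'
#' @param image numeric matrix.
#' @param kernel numeric matrix no larger than the image.
#' @param stride positive integer shift in pixels.
#' @return the feature map matrix.
#' @examples
#' img <- matrix(c(0, 0, 0, 1, 1, 1, 0, 1, 0, 1, 1, 0, 1, 0, 1, 0), 4, 4)
#' convolve2d_valid(img, matrix(1, 2, 2))  # 3x3 feature map
#' @export
convolve2d_valid <- function(image, kernel, stride = 1L) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (stride < 1) stop("stride must be >= 1")
  if (kh > nrow(image) || kw > ncol(image))
    stop("kernel is larger than the image")
  oh <- (nrow(image) - kh) %/% stride + 1L
  ow <- (ncol(image) - kw) %/% stride + 1L
  out <- matrix(0, oh, ow)
  for (j in seq_len(ow)) {
    for (i in seq_len(oh)) {
      r <- (i - 1L) * stride; c <- (j - 1L) * stride
      out[i, j] <- sum(image[r + seq_len(kh), c + seq_len(kw)] * kernel)
    }
  }
  out
}

## ---- internal layer primitives ------------------------------------------
## Batched activations: matrix with N*H*W rows (image slowest, then column,
## then row) and C columns; "bdim" = c(N, H, W) travels alongside.

batch_from_arrays <- function(arrs) {
  d <- dim(arrs[[1]])
  m <- matrix(0, length(arrs) * d[1] * d[2], d[3])
  for (n in seq_along(arrs)) {
    rows <- (n - 1L) * d[1] * d[2] + seq_len(d[1] * d[2])
    for (ch in seq_len(d[3])) m[rows, ch] <- as.vector(arrs[[n]][, , ch])
  }
  structure(m, bdim = c(length(arrs), d[1], d[2]))
}

new_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  # He normal, fan-out mode (the standard ResNet initialization)
  sd <- sqrt(2 / (k * k * cout))
  list(type = "conv", kh = k, kw = k, stride = as.integer(stride),
       pad = as.integer(pad), cin = cin, cout = cout,
       W = matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout))
}

new_fc <- function(cin, cout) {
  # uniform in +/- 1/sqrt(fan_in), the standard linear-layer default
  k <- 1 / sqrt(cin)
  list(W = matrix(runif(cin * cout, -k, k), cin, cout),
       b = runif(cout, -k, k))
}

new_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = rep(0, c),
       rmean = rep(0, c), rvar = rep(1, c), momentum = 0.1, eps = 1e-5)
}

conv_fwd <- function(layer, x, bdim) {
  N <- bdim[1]; H <- bdim[2]; W <- bdim[3]
  col <- im2col_batch(x, H, W, N, layer$kh, layer$kw, layer$stride, layer$pad)
  oh <- (H + 2L * layer$pad - layer$kh) %/% layer$stride + 1L
  ow <- (W + 2L * layer$pad - layer$kw) %/% layer$stride + 1L
  list(y = col %*% layer$W, bdim = c(N, oh, ow),
       cache = list(col = col, bdim_in = bdim))
}

conv_bwd <- function(layer, cache, dy) {
  bi <- cache$bdim_in
  dW <- crossprod(cache$col, dy)
  dcol <- tcrossprod(dy, layer$W)
  dx <- col2im_batch(dcol, bi[2], bi[3], layer$cin, bi[1],
                     layer$kh, layer$kw, layer$stride, layer$pad)
  list(grads = list(W = dW), dx = dx)
}

bn_fwd <- function(layer, x, training) {
  if (training) {
    mu <- .colMeans(x, nrow(x), ncol(x))
    mu2 <- .colMeans(x * x, nrow(x), ncol(x))
    v <- pmax(mu2 - mu * mu, 0)
    inv <- 1 / sqrt(v + layer$eps)
    xhat <- col_standardize(x, mu, inv)
    layer$rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * mu
    layer$rvar <- (1 - layer$momentum) * layer$rvar + layer$momentum * v
  } else {
    inv <- 1 / sqrt(layer$rvar + layer$eps)
    xhat <- col_standardize(x, layer$rmean, inv)
  }
  list(y = col_affine(xhat, layer$gamma, layer$beta), layer = layer,
       cache = list(xhat = xhat, inv = inv))
}

bn_bwd <- function(layer, cache, dy) {
  dgamma <- .colMeans(dy * cache$xhat, nrow(dy), ncol(dy)) * nrow(dy)
  dbeta <- .colMeans(dy, nrow(dy), ncol(dy)) * nrow(dy)
  dxhat <- col_affine(dy, layer$gamma, numeric(ncol(dy)))
  t1 <- dbeta / nrow(dy) * layer$gamma
  t2 <- dgamma / nrow(dy) * layer$gamma
  dx <- bn_backward_dx(dxhat, cache$xhat, t1, t2, cache$inv)
  list(grads = list(gamma = dgamma, beta = dbeta), dx = dx)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

## ---- residual blocks -----------------------------------------------------

#' Construct a residual block
#'
#' Two 3x3 convolution + batch-norm pairs with a ReLU between them form the
#' inner transform `f`; the block output is `x + f(x, w)`. When the block
#' changes resolution or width, the skip path applies a strided 1x1
#' projection convolution with its own batch norm (the standard option-B
#' shortcut), otherwise the input is carried through unchanged.
#'
#' @param cin,cout input/output channel counts.
#' @param stride stride of the first convolution (2 when downsampling).
#' @return a block parameter list.
#' @export
make_residual_block <- function(cin, cout, stride = 1L) {
  blk <- list(conv1 = new_conv(cin, cout, 3L, stride),
              bn1 = new_bn(cout),
              conv2 = new_conv(cout, cout, 3L, 1L),
              bn2 = new_bn(cout),
              stride = as.integer(stride))
  if (stride != 1L || cin != cout) {
    blk$proj_conv <- new_conv(cin, cout, 1L, stride, pad = 0L)
    blk$proj_bn <- new_bn(cout)
  }
  blk
}

block_fwd <- function(blk, x, bdim, training) {
  c1 <- conv_fwd(blk$conv1, x, bdim)
  b1 <- bn_fwd(blk$bn1, c1$y, training); blk$bn1 <- b1$layer
  r1 <- relu_fwd(b1$y)
  c2 <- conv_fwd(blk$conv2, r1$y, c1$bdim)
  b2 <- bn_fwd(blk$bn2, c2$y, training); blk$bn2 <- b2$layer
  if (!is.null(blk$proj_conv)) {
    p <- conv_fwd(blk$proj_conv, x, bdim)
    pb <- bn_fwd(blk$proj_bn, p$y, training); blk$proj_bn <- pb$layer
    skip <- pb$y
    pcache <- list(conv = p$cache, bn = pb$cache)
  } else {
    skip <- x
    pcache <- NULL
  }
  list(y = b2$y + skip, bdim = c2$bdim, blk = blk,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, proj = pcache))
}

block_bwd <- function(blk, cache, dy) {
  g <- list()
  b2 <- bn_bwd(blk$bn2, cache$b2, dy); g$bn2 <- b2$grads
  c2 <- conv_bwd(blk$conv2, cache$c2, b2$dx); g$conv2 <- c2$grads
  dr1 <- c2$dx * cache$r1
  b1 <- bn_bwd(blk$bn1, cache$b1, dr1); g$bn1 <- b1$grads
  c1 <- conv_bwd(blk$conv1, cache$c1, b1$dx); g$conv1 <- c1$grads
  dx <- c1$dx
  if (!is.null(blk$proj_conv)) {
    pb <- bn_bwd(blk$proj_bn, cache$proj$bn, dy); g$proj_bn <- pb$grads
    pc <- conv_bwd(blk$proj_conv, cache$proj$conv, pb$dx); g$proj_conv <- pc$grads
    dx <- dx + pc$dx
  } else {
    dx <- dx + dy
  }
  list(grads = g, dx = dx)
}

#' Forward pass through one residual block
#'
#' Computes `x + f(x, w)`: the skip connection carries the input forward
#' unchanged (or through the 1x1 projection when shapes change) and the
#' two-convolution inner transform contributes only the residual. The final
#' ReLU that the full network applies between blocks is not included, so
#' with all block weights zero the output equals the input exactly.
#'
#' @param x input activation: an `H x W x C` array (single image).
#' @param block a block from [make_residual_block()].
#' @param training use batch statistics (`TRUE`) or running statistics in
#'   the batch norms.
#' @return activation array of the block's output shape.
#' @export
residual_block_forward <- function(x, block, training = TRUE) {
  stopifnot(length(dim(x)) == 3)
  if (dim(x)[3] != block$conv1$cin)
    stop("input has ", dim(x)[3], " channels but block expects ",
         block$conv1$cin)
  xb <- batch_from_arrays(list(x))
  out <- block_fwd(block, xb, attr(xb, "bdim"), training)
  array(out$y, c(out$bdim[2], out$bdim[3], ncol(out$y)))
}

## ---- full network --------------------------------------------------------

#' Build a width-scalable ResNet-18 classifier
#'
#' Standard ResNet-18 topology: a 7x7/2 stem convolution with batch norm,
#' ReLU and 3x3/2 max pooling, four stages of two residual blocks with stage
#' widths `64/128/256/512` scaled by `width_mult`, global average pooling,
#' and a fully connected `num_classes`-way head. Weights use He
#' initialization from the current RNG stream (or `seed`).
#'
#' @param width_mult positive width multiplier; 1 is the full network,
#'   fractional values give desk-scale variants.
#' @param num_classes size of the classification head (default 2).
#' @param in_channels input channels (3: grayscale crops are replicated).
#' @param seed optional integer seed for the initialization draws.
#' @return object of class `fission_net`.
#' @export
build_network <- function(width_mult = 1, num_classes = 2L,
                          in_channels = 3L, seed = NULL) {
  if (width_mult <= 0) stop("width_mult must be positive")
  if (num_classes < 2) stop("num_classes must be at least 2")
  widths <- pmax(1L, as.integer(round(c(64, 128, 256, 512) * width_mult)))
  build <- function() {
    net <- list(spec = list(width_mult = width_mult, widths = widths,
                            blocks = c(2L, 2L, 2L, 2L),
                            num_classes = as.integer(num_classes),
                            in_channels = as.integer(in_channels)),
                stem = list(conv = new_conv(in_channels, widths[1], 7L, 2L),
                            bn = new_bn(widths[1])),
                stages = vector("list", 4))
    cin <- widths[1]
    for (s in 1:4) {
      blocks <- list()
      for (b in 1:2) {
        stride <- if (s > 1 && b == 1) 2L else 1L
        blocks[[b]] <- make_residual_block(if (b == 1) cin else widths[s],
                                           widths[s], stride)
      }
      net$stages[[s]] <- blocks
      cin <- widths[s]
    }
    net$fc <- new_fc(widths[4], num_classes)
    class(net) <- "fission_net"
    net
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' @export
print.fission_net <- function(x, ...) {
  cat(sprintf("ResNet-18 classifier (width_mult %.3g, widths %s, %d classes)\n",
              x$spec$width_mult, paste(x$spec$widths, collapse = "/"),
              x$spec$num_classes))
  cat(sprintf("  parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a network
#' @param net a `fission_net`.
#' @return integer parameter count.
#' @export
count_parameters <- function(net) {
  n <- 0
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$type) && x$type == "conv") n <<- n + length(x$W)
      else if (!is.null(x$type) && x$type == "bn")
        n <<- n + length(x$gamma) + length(x$beta)
      else for (el in x) if (is.list(el)) walk(el)
    }
  }
  walk(net$stem); walk(net$stages)
  n + length(net$fc$W) + length(net$fc$b)
}

net_forward <- function(net, x, training = FALSE, with_cache = FALSE) {
  bdim <- attr(x, "bdim")
  cache <- list()
  sc <- conv_fwd(net$stem$conv, x, bdim)
  sb <- bn_fwd(net$stem$bn, sc$y, training); net$stem$bn <- sb$layer
  sr <- relu_fwd(sb$y)
  N <- sc$bdim[1]
  mp <- maxpool_forward(sr$y, sc$bdim[2], sc$bdim[3], N, 3L, 2L, 1L)
  oh <- (sc$bdim[2] + 2L - 3L) %/% 2L + 1L
  ow <- (sc$bdim[3] + 2L - 3L) %/% 2L + 1L
  h <- mp$y; bdim <- c(N, oh, ow)
  if (with_cache)
    cache$stem <- list(conv = sc$cache, bn = sb$cache, relu = sr$cache,
                       pool_arg = mp$argmax, pool_in_rows = nrow(sr$y),
                       pool_bdim = sc$bdim)
  stage_caches <- vector("list", 4)
  for (s in 1:4) {
    blk_caches <- vector("list", length(net$stages[[s]]))
    for (b in seq_along(net$stages[[s]])) {
      out <- block_fwd(net$stages[[s]][[b]], h, bdim, training)
      net$stages[[s]][[b]] <- out$blk
      r <- relu_fwd(out$y)
      h <- r$y; bdim <- out$bdim
      if (with_cache) blk_caches[[b]] <- list(block = out$cache, relu = r$cache)
    }
    stage_caches[[s]] <- blk_caches
  }
  if (with_cache) cache$stages <- stage_caches
  hw <- bdim[2] * bdim[3]
  grp <- rep(seq_len(bdim[1]), each = hw)
  pooled <- rowsum(h, grp) / hw
  scores <- pooled %*% net$fc$W +
    matrix(net$fc$b, bdim[1], length(net$fc$b), byrow = TRUE)
  if (with_cache) cache$head <- list(pooled = pooled, hw = hw, bdim = bdim)
  list(scores = scores, net = net, cache = if (with_cache) cache else NULL)
}

net_backward <- function(net, cache, dscores) {
  g <- list(fc = list(W = crossprod(cache$head$pooled, dscores),
                      b = colSums(dscores)))
  bdim <- cache$head$bdim; hw <- cache$head$hw
  dpooled <- tcrossprod(dscores, net$fc$W)
  dh <- dpooled[rep(seq_len(bdim[1]), each = hw), , drop = FALSE] / hw
  g$stages <- vector("list", 4)
  for (s in 4:1) {
    nb <- length(net$stages[[s]])
    g$stages[[s]] <- vector("list", nb)
    for (b in nb:1) {
      cc <- cache$stages[[s]][[b]]
      dh <- dh * cc$relu
      bw <- block_bwd(net$stages[[s]][[b]], cc$block, dh)
      g$stages[[s]][[b]] <- bw$grads
      dh <- bw$dx
    }
  }
  st <- cache$stem
  dh <- maxpool_backward(dh, st$pool_arg, st$pool_in_rows)
  dh <- dh * st$relu
  sb <- bn_bwd(net$stem$bn, st$bn, dh); g$stem <- list(bn = sb$grads)
  sc <- conv_bwd(net$stem$conv, st$conv, sb$dx); g$stem$conv <- sc$grads
  g
}

softmax_xent <- function(scores, labels) {
  # labels are 0-based class ids
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  p <- e / rowSums(e)
  n <- nrow(scores)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dscores = d / n, probs = p)
}

#' Save / load a network checkpoint
#'
#' Checkpoints are the full `fission_net` structure (weights, batch-norm
#' running statistics and topology spec) serialized with [saveRDS()].
#'
#' @param net a `fission_net`.
#' @param path checkpoint file.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the network.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "fission_net")) stop("not a fission_net checkpoint")
  net
}

#' Initialize a network from a pretrained checkpoint (transfer learning)
#'
#' Copies every layer except the fully connected head from the checkpoint
#' into a network of matching topology, then re-initializes the head for
#' `num_classes` outputs. All layers remain trainable (full fine-tuning).
#'
#' @param network target `fission_net` (defines the expected topology).
#' @param checkpoint a `fission_net` or a path to one saved with
#'   [save_checkpoint()]. Its head may have any number of outputs.
#' @param num_classes output count of the new head.
#' @param seed optional seed for the head re-initialization.
#' @return the network with transferred weights.
#' @export
load_pretrained <- function(network, checkpoint, num_classes = 2L,
                            seed = NULL) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  bad <- character()
  sig <- function(conv) paste(dim(conv$W), collapse = "x")
  check_blk <- function(a, b, tag) {
    for (nm in c("conv1", "conv2", "proj_conv")) {
      if (is.null(a[[nm]]) != is.null(b[[nm]]) ||
          (!is.null(a[[nm]]) && sig(a[[nm]]) != sig(b[[nm]])))
        bad <<- c(bad, paste0(tag, "$", nm))
    }
  }
  if (sig(network$stem$conv) != sig(ck$stem$conv)) bad <- c(bad, "stem$conv")
  for (s in 1:4) for (b in 1:2)
    check_blk(network$stages[[s]][[b]], ck$stages[[s]][[b]],
              sprintf("stage%d$block%d", s, b))
  if (length(bad))
    stop("checkpoint topology mismatch in: ", paste(bad, collapse = ", "))
  network$stem <- ck$stem
  network$stages <- ck$stages
  cfeat <- nrow(network$fc$W)
  network$fc <- if (is.null(seed)) new_fc(cfeat, num_classes) else
    with_seed(seed, new_fc(cfeat, num_classes))
  network$spec$num_classes <- as.integer(num_classes)
  network
}
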