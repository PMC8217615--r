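#' Stochastic gradient descent state
#'
#' Holds the parameter vector `theta`, its velocity `v` (initialized to
#' zero), the learning rate `alpha`, the momentum factor `mu`, and the
#' iteration counter `t`.
#'
#' @param theta numeric parameter vector (any shape).
#' @param alpha learning rate, positive.
#' @param mu momentum factor in `[0, 1)`.
#' @return object of class `sgd_state`.
#' @export
sgd_state <- function(theta, alpha = 0.001, mu = 0.9) {
  if (alpha <= 0) stop("learning rate alpha must be positive")
  if (mu < 0 || mu >= 1) stop("momentum mu must lie in [0, 1)")
  structure(list(theta = theta, v = theta * 0, alpha = alpha, mu = mu,
                 t = 0L),
            class = "sgd_state")
}

#' One SGD-with-momentum update
#'
#' Applies the two-step momentum update: the velocity accumulates the
#' gradient, `v' = mu * v + alpha * g`, and the parameters move against it,
#' `theta' = theta - v'`. With `mu = 0` this reduces to plain (stochastic)
#' gradient descent `theta' = theta - alpha * g`. The gradient `g` is the
#' minibatch average of the per-item loss gradients.
#'
#' @param state an [sgd_state()].
#' @param grad numeric gradient of the same shape as `theta`.
#' @return the updated state (velocity, parameters, `t` incremented).
#' @examples
#' s <- sgd_state(1, alpha = 0.1, mu = 0.9)
#' s <- sgd_step(s, s$theta)  # gradient of theta^2/2 is theta
#' s$theta  # 0.9
#' @export
sgd_step <- function(state, grad) {
  stopifnot(inherits(state, "sgd_state"))
  if (any(!is.finite(grad))) stop("non-finite gradient in sgd_step")
  if (length(grad) != length(state$theta))
    stop("gradient shape does not match theta")
  state$v <- state$mu * state$v + state$alpha * grad
  state$theta <- state$theta - state$v
  state$t <- state$t + 1L
  state
}

#' Step learning-rate decay schedule
#'
#' Every `period` epochs the learning rate undergoes the substitution
#' `alpha = gamma * alpha`, so at (0-based) epoch `e` the rate is
#' `alpha0 * gamma^floor(e / period)`.
#'
#' @param period decay period in epochs (default 7).
#' @param gamma multiplicative decay factor in `(0, 1]` (default 0.1).
#' @return object of class `lr_schedule`.
#' @export
lr_schedule <- function(period = 7L, gamma = 0.1) {
  if (period < 1) stop("period must be >= 1")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  structure(list(period = as.integer(period), gamma = gamma),
            class = "lr_schedule")
}

#' @rdname lr_schedule
#' @param schedule an `lr_schedule`.
#' @param epoch 0-based epoch counter.
#' @param alpha current learning rate (for [lr_step()]) or the initial rate
#'   (for [lr_at()]).
#' @details `lr_step()` is the per-epoch substitution form: it returns
#'   `gamma * alpha` when `epoch` is a positive multiple of `period` and
#'   `alpha` unchanged otherwise. `lr_at()` is the equivalent closed form
#'   `alpha * gamma^floor(epoch / period)` from the initial rate.
#' @export
lr_step <- function(schedule, epoch, alpha) {
  stopifnot(inherits(schedule, "lr_schedule"), epoch >= 0)
  if (epoch > 0 && epoch %% schedule$period == 0) schedule$gamma * alpha
  else alpha
}

#' @rdname lr_schedule
#' @export
lr_at <- function(schedule, epoch, alpha) {
  stopifnot(inherits(schedule, "lr_schedule"), epoch >= 0)
  alpha * schedule$gamma^(epoch %/% schedule$period)
}

#' Compensated (Kahan) accumulator
#'
#' A running sum `S` with a residual term `R` that records the rounding
#' error of each addition and feeds it back into the next one, so long sums
#' retain close to double-precision accuracy even when the working
#' precision is much coarser. One update performs exactly
#' `T = S; U = x + R; S = S + U; R = U - (S - T)`.
#'
#' @return `kahan_new()` returns a fresh accumulator (S = 0, R = 0).
#' @export
kahan_new <- function() list(s = 0, r = 0)

#' @rdname kahan_new
#' @param acc an accumulator from [kahan_new()].
#' @param x finite value(s) to add (vectors are added element by element).
#' @export
kahan_add <- function(acc, x) {
  if (any(!is.finite(x))) stop("non-finite input to kahan_add")
  for (xi in x) {
    tt <- acc$s
    u <- xi + acc$r
    acc$s <- tt + u
    acc$r <- u - (acc$s - tt)
  }
  acc
}

#' @rdname kahan_new
#' @export
kahan_value <- function(acc) acc$s

#' Single-precision summation demonstrations
#'
#' Sums a vector in genuine 32-bit float arithmetic, either naively
#' (`compensated = FALSE`) or with the compensated recursion. Useful for
#' demonstrating that compensation yields double-precision-like results
#' even when computed in single precision.
#'
#' @param x numeric vector (each element rounded to float before adding).
#' @param compensated carry the Kahan residual.
#' @return the sum, as a double holding the float result.
#' @export
sum_single_precision <- function(x, compensated = TRUE) {
  if (any(!is.finite(x))) stop("non-finite input")
  if (compensated) sum_float_kahan(x) else sum_float_naive(x)
}

## Internal: SGD update applied across a nested parameter structure (the
## network). Velocities mirror the gradients; each tensor follows the same
## v' = mu*v + alpha*g, theta' = theta - v' update as sgd_step.
sgd_update_tree <- function(params, vel, grads, alpha, mu) {
  if (is.null(vel)) vel <- vector("list", length(grads))
  if (length(vel) < length(grads))
    vel <- c(vel, vector("list", length(grads) - length(vel)))
  nms <- names(grads)
  for (i in seq_along(grads)) {
    key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
    g <- grads[[i]]
    if (is.numeric(g)) {
      if (any(!is.finite(g))) stop("non-finite gradient for parameter ", key)
      v <- if (is.null(vel[[i]])) g * 0 else vel[[i]]
      v <- mu * v + alpha * g
      params[[key]] <- params[[key]] - v
      vel[[i]] <- v
    } else if (is.list(g)) {
      r <- sgd_update_tree(params[[key]], vel[[i]], g, alpha, mu)
      params[[key]] <- r$params
      vel[[i]] <- r$vel
    }
  }
  list(params = params, vel = vel)
}
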