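# Minimal neural-network primitives on 5-D arrays [H, W, B, C, N].
#
# Every primitive comes as a forward (returning the output plus a cache) and a
# backward (consuming the cache and the upstream gradient).  The model-level
# code chains these by hand; correctness of every backward pass is checked by
# finite differences in the test suite.

# ---- shape helpers ---------------------------------------------------------

as_batch5 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 3L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 4L) dim(x) <- c(d, 1L)
  else if (length(d) != 5L) stop("expected a 3-, 4- or 5-D array")
  x
}

same_pad <- function(kernel) as.integer((kernel - 1L) %/% 2L)

# Move the channel axis (4th of 5) last and flatten: [H*W*B*N, C]
.channel_matrix <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 3L, 5L, 4L))
  dim(m) <- c(prod(d[-4L]), d[4L])
  m
}

.channel_unmatrix <- function(m, d) {
  dim(m) <- d[c(1L, 2L, 3L, 5L, 4L)]
  aperm(m, c(1L, 2L, 3L, 5L, 4L))
}

# ---- convolution -----------------------------------------------------------

#' @noRd
nn_conv3d_forward <- function(x, w, bias = NULL, pad = NULL, stride = c(1L, 1L, 1L)) {
  kd <- dim(w)[1:3]
  if (is.null(pad)) pad <- same_pad(kd)
  y <- cpp_conv3d_forward(x, w, as.integer(pad), as.integer(stride))
  if (!is.null(bias)) {
    d <- dim(y)
    y <- y + rep(rep(bias, each = prod(d[1:3])), times = d[5L])
  }
  list(y = y, cache = list(x = x, w = w, bias = bias,
                           pad = as.integer(pad), stride = as.integer(stride)))
}

#' @noRd
nn_conv3d_backward <- function(cache, dy) {
  g <- cpp_conv3d_backward(cache$x, cache$w, dy, cache$pad, cache$stride)
  db <- NULL
  if (!is.null(cache$bias)) {
    d <- dim(dy)
    db <- colSums(matrix(aperm(dy, c(1L, 2L, 3L, 5L, 4L)), ncol = d[4L]))
  }
  list(dx = g$dx, dw = g$dw, db = db)
}

# ---- pooling and resizing --------------------------------------------------

pool_target_dim <- function(size, window) {
  pmax(1L, as.integer(size) %/% pmax(1L, as.integer(window)))
}

#' @noRd
nn_maxpool3d_forward <- function(x, window = c(2L, 2L, 2L), target = NULL) {
  d <- dim(x)
  if (is.null(target)) target <- pool_target_dim(d[1:3], window)
  out <- cpp_maxpool3d_forward(x, as.integer(target))
  list(y = out$y, cache = list(idx = out$idx, xdim = d))
}

#' @noRd
nn_maxpool3d_backward <- function(cache, dy) {
  cpp_maxpool3d_backward(dy, cache$idx, as.integer(cache$xdim))
}

#' @noRd
nn_upsample3d_forward <- function(x, target) {
  list(y = cpp_upsample3d_forward(x, as.integer(target)),
       cache = list(xdim = dim(x)))
}

#' @noRd
nn_upsample3d_backward <- function(cache, dy) {
  cpp_upsample3d_backward(dy, as.integer(cache$xdim))
}

# ---- batch normalization ---------------------------------------------------

# Per-channel batch statistics over all voxels and samples; epsilon defaults
# to 1e-4 (the stability constant the architecture prescribes).
#' @noRd
nn_bn_init <- function(channels, eps = 1e-4, momentum = 0.1) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       running_mean = rep(0, channels), running_var = rep(1, channels),
       eps = eps, momentum = momentum)
}

#' @noRd
nn_bn_forward <- function(x, bn, training = TRUE) {
  d <- dim(x)
  m <- .channel_matrix(x)
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu)
    va <- colMeans(xc * xc)
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
    xc <- sweep(m, 2L, mu)
  }
  istd <- 1 / sqrt(va + bn$eps)
  xh <- sweep(xc, 2L, istd, `*`)
  y <- sweep(sweep(xh, 2L, bn$gamma, `*`), 2L, bn$beta, `+`)
  state <- NULL
  if (training) {
    state <- list(
      running_mean = (1 - bn$momentum) * bn$running_mean + bn$momentum * mu,
      running_var  = (1 - bn$momentum) * bn$running_var + bn$momentum * va)
  }
  list(y = .channel_unmatrix(y, d),
       cache = list(xh = xh, istd = istd, gamma = bn$gamma, d = d,
                    training = training),
       state = state)
}

#' @noRd
nn_bn_backward <- function(cache, dy) {
  d <- cache$d
  dym <- .channel_matrix(dy)
  dgamma <- colSums(dym * cache$xh)
  dbeta <- colSums(dym)
  m <- nrow(dym)
  dxh <- sweep(dym, 2L, cache$gamma, `*`)
  if (cache$training) {
    # full train-mode derivative through the batch mean and variance
    t1 <- sweep(dxh, 2L, colMeans(dxh))
    t2 <- sweep(cache$xh, 2L, colMeans(dxh * cache$xh), `*`)
    dxm <- sweep(t1 - t2, 2L, cache$istd, `*`)
  } else {
    dxm <- sweep(dxh, 2L, cache$istd, `*`)
  }
  list(dx = .channel_unmatrix(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations -----------------------------------------------------------

#' Mish activation
#'
#' `mish(x) = x * tanh(softplus(x))` -- the smooth non-monotonic activation
#' used throughout the pyramidal feature-extraction blocks.
#'
#' @param x numeric vector or array.
#' @return object of the same shape as `x`.
#' @export
mish <- function(x) {
  sp <- log1p(exp(pmin(x, 20)))
  hi <- x > 20
  if (any(hi)) sp[hi] <- x[hi]
  x * tanh(sp)
}

#' @noRd
nn_mish_forward <- function(x) list(y = mish(x), cache = list(x = x))

#' @noRd
nn_mish_backward <- function(cache, dy) {
  x <- cache$x
  sp <- log1p(exp(pmin(x, 20)))
  hi <- x > 20
  if (any(hi)) sp[hi] <- x[hi]
  tsp <- tanh(sp)
  sig <- 1 / (1 + exp(-x))
  dy * (tsp + x * (1 - tsp^2) * sig)
}

#' @noRd
nn_relu_forward <- function(x) list(y = pmax(x, 0), cache = list(mask = x > 0))

#' @noRd
nn_relu_backward <- function(cache, dy) dy * cache$mask

# ---- dense, dropout, softmax ----------------------------------------------

#' @noRd
nn_dense_forward <- function(x, w, b) {
  # x: [features, N]
  list(y = crossprod(w, x) + b, cache = list(x = x, w = w))
}

#' @noRd
nn_dense_backward <- function(cache, dy) {
  list(dx = cache$w %*% dy,
       dw = cache$x %*% t(dy),
       db = rowSums(dy))
}

#' @noRd
nn_dropout_forward <- function(x, p, training = TRUE) {
  if (!training || p <= 0) return(list(y = x, cache = list(mask = NULL)))
  mask <- array(stats::runif(length(x)) >= p, dim = dim(x)) / (1 - p)
  list(y = x * mask, cache = list(mask = mask))
}

#' @noRd
nn_dropout_backward <- function(cache, dy) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# Numerically stable column-wise softmax ([classes, N])
#' @noRd
nn_softmax <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# Cross-entropy loss with integrated softmax backward.
# labels: integer class index 1..K per column.
#' @noRd
nn_softmax_ce <- function(z, labels) {
  p <- nn_softmax(z)
  n <- ncol(z)
  picked <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dz <- p
  dz[cbind(labels, seq_len(n))] <- dz[cbind(labels, seq_len(n))] - 1
  list(loss = loss, probs = p, dz = dz / n)
}

# ---- parameter containers and Adam ----------------------------------------

# Parameters live in a flat named list of numeric arrays; gradients mirror it.

#' @noRd
nn_init_weight <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' @noRd
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

#' @noRd
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    d0 <- dim(params[[nm]])
    upd <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (is.null(d0)) upd <- as.numeric(upd) else dim(upd) <- d0
    params[[nm]] <- upd
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accumulate gradient lists (named, possibly overlapping)
#' @noRd
grad_acc <- function(acc, g) {
  for (nm in names(g)) {
    if (is.null(g[[nm]])) next
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}
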