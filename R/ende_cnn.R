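# Encoder-decoder classifier: 3-D convolutional encoder with multilayer
# feature concatenation, mirrored decoder trained with a reconstruction loss,
# and a fully connected detection head.

#' Convolution output size along one axis
#'
#' `floor((M_prev + 2 * pad - kernel) / stride) + 1` (dilation 1).
#'
#' @param m_prev input size (>= 0).
#' @param pad per-side padding (>= 0).
#' @param kernel kernel size (>= 1).
#' @param stride stride (>= 1).
#' @param axis axis name used in error messages.
#' @return integer output size.
#' @export
conv_output_size <- function(m_prev, pad = 0L, kernel = 1L, stride = 1L,
                             axis = "axis") {
  if (m_prev < 0 || pad < 0) stop("sizes and padding must be >= 0")
  if (kernel < 1 || stride < 1) stop("kernel and stride must be >= 1")
  if (kernel > m_prev + 2 * pad)
    stop("size error on ", axis, ": kernel ", kernel,
         " larger than padded input ", m_prev + 2 * pad)
  as.integer((m_prev + 2 * pad - kernel) %/% stride + 1L)
}

#' EnDe-CNN configuration
#'
#' @param stage_channels channels of the three encoder stages.
#' @param taps encoder stages whose outputs are concatenated into the latent
#'   (pooled to the deepest spatial size first).
#' @param dropout dropout probability of the detection head.
#' @param n_classes number of output classes (>= 2).
#' @param lambda_rec weight of the reconstruction loss in the joint training
#'   objective.
#' @return a config list.
#' @export
ende_config <- function(stage_channels = c(16L, 32L, 64L), taps = 1:3,
                        dropout = 0.3, n_classes = 2L, lambda_rec = 0.1) {
  if (n_classes < 2L) stop("config error: n_classes must be >= 2")
  if (any(taps < 1L) || any(taps > length(stage_channels)))
    stop("config error: tap depth out of range")
  list(stage_channels = as.integer(stage_channels), taps = as.integer(taps),
       dropout = dropout, n_classes = as.integer(n_classes),
       lambda_rec = lambda_rec)
}

#' Initialize the encoder-decoder classifier
#'
#' Shapes are precomputed from the input volume dimensions: each stage is a
#' same-padded 3 x 3 x 3 convolution + batch norm + ReLU, with 2 x 2 x 2 max
#' pooling between stages; the decoder mirrors the encoder with
#' upsample-and-convolve (deconvolution) stages back to the input shape.
#'
#' @param in_dim input spatial dims `c(H, W, B)`.
#' @param in_channels input channel count.
#' @param cfg an [ende_config()].
#' @return network object with flat `params`, `state` and shape bookkeeping.
#' @export
ende_init <- function(in_dim, in_channels, cfg = ende_config()) {
  sc <- cfg$stage_channels
  n_stage <- length(sc)
  params <- list(); state <- list()
  dims <- list(as.integer(in_dim))     # spatial dims entering each stage
  cins <- c(in_channels, sc[-n_stage])
  for (l in seq_len(n_stage)) {
    params[[paste0("enc", l, ".w")]] <-
      nn_init_weight(c(3L, 3L, 3L, cins[l], sc[l]), 27 * cins[l])
    params[[paste0("enc", l, ".bn.gamma")]] <- rep(1, sc[l])
    params[[paste0("enc", l, ".bn.beta")]] <- rep(0, sc[l])
    state[[paste0("enc", l, ".bn.mean")]] <- rep(0, sc[l])
    state[[paste0("enc", l, ".bn.var")]] <- rep(1, sc[l])
    d <- dims[[l]]
    dims[[l + 1L]] <- if (l < n_stage) pool_target_dim(d, c(2L, 2L, 2L)) else d
  }
  # stage OUTPUT spatial dims: pooled for 1..n-1, unpooled for the last
  out_dims <- dims[-1L]
  deepest <- out_dims[[n_stage]]
  latent_channels <- sum(sc[cfg$taps])
  # decoder mirrors the encoder: deepest -> ... -> input shape
  dec_couts <- c(rev(sc)[-1L], in_channels)
  dec_cins <- c(latent_channels, dec_couts[-n_stage])
  dec_targets <- c(rev(out_dims)[-1L], list(as.integer(in_dim)))
  for (l in seq_len(n_stage)) {
    params[[paste0("dec", l, ".w")]] <-
      nn_init_weight(c(3L, 3L, 3L, dec_cins[l], dec_couts[l]),
                     27 * dec_cins[l])
    if (l < n_stage) {
      params[[paste0("dec", l, ".bn.gamma")]] <- rep(1, dec_couts[l])
      params[[paste0("dec", l, ".bn.beta")]] <- rep(0, dec_couts[l])
      state[[paste0("dec", l, ".bn.mean")]] <- rep(0, dec_couts[l])
      state[[paste0("dec", l, ".bn.var")]] <- rep(1, dec_couts[l])
    } else {
      params[[paste0("dec", l, ".b")]] <- rep(0, dec_couts[l])
    }
  }
  feat <- prod(deepest) * latent_channels
  params[["head.w"]] <- matrix(stats::rnorm(feat * cfg$n_classes,
                                            sd = sqrt(1 / feat)),
                               feat, cfg$n_classes)
  params[["head.b"]] <- rep(0, cfg$n_classes)
  list(params = params, state = state, cfg = cfg,
       in_dim = as.integer(in_dim), in_channels = in_channels,
       out_dims = out_dims, deepest = deepest,
       latent_channels = latent_channels, dec_targets = dec_targets)
}

# conv(same) + BN + ReLU
cbr_forward <- function(x, w, gamma, beta, mean_s, var_s, training) {
  cv <- nn_conv3d_forward(x, w)
  bn <- list(gamma = gamma, beta = beta, running_mean = mean_s,
             running_var = var_s, eps = 1e-4, momentum = 0.1)
  bf <- nn_bn_forward(cv$y, bn, training)
  rf <- nn_relu_forward(bf$y)
  list(y = rf$y, cache = list(cv = cv$cache, bn = bf$cache, re = rf$cache),
       state = bf$state)
}

cbr_backward <- function(cache, dy) {
  dz <- nn_relu_backward(cache$re, dy)
  bb <- nn_bn_backward(cache$bn, dz)
  cb <- nn_conv3d_backward(cache$cv, bb$dx)
  list(dx = cb$dx, dw = cb$dw, dgamma = bb$dgamma, dbeta = bb$dbeta)
}

ende_encode_forward <- function(x5, net, training = FALSE) {
  sc <- net$cfg$stage_channels
  n_stage <- length(sc)
  caches <- list(); pools <- list(); stage_out <- list()
  new_state <- list()
  h <- x5
  for (l in seq_len(n_stage)) {
    f <- cbr_forward(h, net$params[[paste0("enc", l, ".w")]],
                     net$params[[paste0("enc", l, ".bn.gamma")]],
                     net$params[[paste0("enc", l, ".bn.beta")]],
                     net$state[[paste0("enc", l, ".bn.mean")]],
                     net$state[[paste0("enc", l, ".bn.var")]], training)
    caches[[l]] <- f$cache
    if (!is.null(f$state)) {
      new_state[[paste0("enc", l, ".bn.mean")]] <- f$state$running_mean
      new_state[[paste0("enc", l, ".bn.var")]] <- f$state$running_var
    }
    h <- f$y
    if (l < n_stage) {
      mp <- nn_maxpool3d_forward(h, window = c(2L, 2L, 2L))
      pools[[l]] <- mp$cache
      h <- mp$y
    }
    stage_out[[l]] <- h
  }
  # latent: tapped stage outputs adaptively pooled to the deepest size
  tap_caches <- list(); tapped <- list()
  for (ti in seq_along(net$cfg$taps)) {
    l <- net$cfg$taps[ti]
    if (all(dim(stage_out[[l]])[1:3] == net$deepest)) {
      tapped[[ti]] <- stage_out[[l]]
      tap_caches[ti] <- list(NULL)
    } else {
      ap <- nn_maxpool3d_forward(stage_out[[l]], target = net$deepest)
      tapped[[ti]] <- ap$y
      tap_caches[[ti]] <- ap$cache
    }
  }
  D <- ch_cat(tapped)
  list(D = D, stage_out = stage_out,
       cache = list(caches = caches, pools = pools, tap_caches = tap_caches),
       state = new_state)
}

ende_encode_backward <- function(enc, net, dD, dstage_extra = NULL) {
  sc <- net$cfg$stage_channels
  n_stage <- length(sc)
  taps <- net$cfg$taps
  dstage <- vector("list", n_stage)
  parts <- ch_split(dD, sc[taps])
  for (ti in seq_along(taps)) {
    l <- taps[ti]
    g <- if (is.null(enc$cache$tap_caches[[ti]])) parts[[ti]] else
      nn_maxpool3d_backward(enc$cache$tap_caches[[ti]], parts[[ti]])
    dstage[[l]] <- if (is.null(dstage[[l]])) g else dstage[[l]] + g
  }
  if (!is.null(dstage_extra))
    for (l in seq_len(n_stage))
      if (!is.null(dstage_extra[[l]]))
        dstage[[l]] <- if (is.null(dstage[[l]])) dstage_extra[[l]] else
          dstage[[l]] + dstage_extra[[l]]
  grads <- list()
  dh <- NULL
  for (l in rev(seq_len(n_stage))) {
    g <- dstage[[l]]
    if (is.null(g)) g <- array(0, dim = dim(enc$stage_out[[l]]))
    if (!is.null(dh)) g <- g + dh
    if (l < n_stage) g <- nn_maxpool3d_backward(enc$cache$pools[[l]], g)
    bb <- cbr_backward(enc$cache$caches[[l]], g)
    grads[[paste0("enc", l, ".w")]] <- bb$dw
    grads[[paste0("enc", l, ".bn.gamma")]] <- bb$dgamma
    grads[[paste0("enc", l, ".bn.beta")]] <- bb$dbeta
    dh <- bb$dx
  }
  list(dx = dh, grads = grads)
}

ende_decode_forward <- function(D, net, training = FALSE) {
  n_stage <- length(net$cfg$stage_channels)
  caches <- list(); new_state <- list()
  h <- D
  for (l in seq_len(n_stage)) {
    up <- nn_upsample3d_forward(h, net$dec_targets[[l]])
    if (l < n_stage) {
      f <- cbr_forward(up$y, net$params[[paste0("dec", l, ".w")]],
                       net$params[[paste0("dec", l, ".bn.gamma")]],
                       net$params[[paste0("dec", l, ".bn.beta")]],
                       net$state[[paste0("dec", l, ".bn.mean")]],
                       net$state[[paste0("dec", l, ".bn.var")]], training)
      if (!is.null(f$state)) {
        new_state[[paste0("dec", l, ".bn.mean")]] <- f$state$running_mean
        new_state[[paste0("dec", l, ".bn.var")]] <- f$state$running_var
      }
      caches[[l]] <- list(up = up$cache, cbr = f$cache)
      h <- f$y
    } else {
      cv <- nn_conv3d_forward(up$y, net$params[[paste0("dec", l, ".w")]],
                              bias = net$params[[paste0("dec", l, ".b")]])
      caches[[l]] <- list(up = up$cache, cv = cv$cache)
      h <- cv$y
    }
  }
  list(recon = h, cache = caches, state = new_state)
}

ende_decode_backward <- function(dec, net, drecon) {
  n_stage <- length(net$cfg$stage_channels)
  grads <- list()
  dh <- drecon
  for (l in rev(seq_len(n_stage))) {
    if (l < n_stage) {
      bb <- cbr_backward(dec$cache[[l]]$cbr, dh)
      grads[[paste0("dec", l, ".w")]] <- bb$dw
      grads[[paste0("dec", l, ".bn.gamma")]] <- bb$dgamma
      grads[[paste0("dec", l, ".bn.beta")]] <- bb$dbeta
      dh <- nn_upsample3d_backward(dec$cache[[l]]$up, bb$dx)
    } else {
      cb <- nn_conv3d_backward(dec$cache[[l]]$cv, dh)
      grads[[paste0("dec", l, ".w")]] <- cb$dw
      grads[[paste0("dec", l, ".b")]] <- cb$db
      dh <- nn_upsample3d_backward(dec$cache[[l]]$up, cb$dx)
    }
  }
  list(dD = dh, grads = grads)
}

#' Reconstruction loss
#'
#' Mean over the k feature patches of the squared L2 distance between each
#' patch and its reconstruction: `(1/k) * sum_j || x_j - r_j ||_2^2`.  Zero
#' exactly when the reconstruction equals the input.
#'
#' @param recon reconstruction array; last axis indexes the k patches.
#' @param target target array of the same shape.
#' @param k number of patches; defaults to the size of the last axis.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(recon, target, k = NULL) {
  if (!all(dim(recon) == dim(target)))
    stop("structural error: reconstruction shape ",
         paste(dim(recon), collapse = "x"), " does not match target ",
         paste(dim(target), collapse = "x"))
  if (is.null(k)) k <- dim(recon)[length(dim(recon))]
  sum((recon - target)^2) / k
}

#' Encode fused features into the concatenated latent
#'
#' Three stages of same-padded 3-D convolution + batch norm + ReLU with
#' 2 x 2 x 2 max pooling between stages; the tapped stage outputs are pooled
#' to the deepest spatial size and concatenated channel-wise.
#'
#' @param x input array \[H, W, B, C\] or batch \[H, W, B, C, N\].
#' @param net an [ende_init()] network.
#' @param training logical (batch-norm mode).
#' @return list with `D` (latent, \[H', W', B', sum(tapped channels), N\]),
#'   `stage_out` and the internal cache.
#' @export
encode <- function(x, net, training = FALSE) {
  x <- as_batch5(x)
  if (dim(x)[4L] != net$in_channels)
    stop("structural error: input has ", dim(x)[4L],
         " channels, encoder expects ", net$in_channels)
  ende_encode_forward(x, net, training)
}

#' Decode the latent and compute the reconstruction loss
#'
#' The decoder mirrors the encoder (upsample-and-convolve deconvolution
#' stages with batch norm + ReLU, final linear convolution), restoring the
#' encoder input's shape exactly.
#'
#' @param D latent array from [encode()].
#' @param target the encoder input to reconstruct.
#' @param net an [ende_init()] network.
#' @param training logical (batch-norm mode).
#' @return list with `recon` and scalar `loss`.
#' @export
decode_and_loss <- function(D, target, net, training = FALSE) {
  target <- as_batch5(target)
  dec <- ende_decode_forward(as_batch5(D), net, training)
  list(recon = dec$recon,
       loss = reconstruction_loss(dec$recon, target, k = dim(target)[5L]))
}

#' Classify from the latent
#'
#' Flatten, dropout, dense, softmax.
#'
#' @param D latent array (\[H, W, B, C\] or batched).
#' @param net an [ende_init()] network.
#' @param training logical: apply dropout when `TRUE`.
#' @return matrix \[n_classes, N\] of class probabilities (columns sum to 1).
#' @export
classify <- function(D, net, training = FALSE) {
  D <- as_batch5(D)
  n <- dim(D)[5L]
  flat <- matrix(D, ncol = n)
  dr <- nn_dropout_forward(flat, net$cfg$dropout, training)
  dn <- nn_dense_forward(dr$y, net$params[["head.w"]],
                         net$params[["head.b"]])
  nn_softmax(dn$y)
}
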