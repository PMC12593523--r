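# Feature volumes and the pyramidal spectral/spatial/temporal network.
#
# A 1-D segment becomes a 3-D volume by tiling its log-spectrogram frames
# row-major onto an H x W grid with the reduced spectral axis last, so that
# (1,1,k) kernels act along frequency and (k,k,1)/(k,1,1) kernels act on the
# time-frame structure.

#' Build a 3-D feature volume from a segment
#'
#' Log-magnitude STFT -> frequency bins reduced to `n_bins` by uniform bin
#' averaging -> the T time frames tiled row-major into an H x W grid with
#' `H = W = ceiling(sqrt(T))` (missing cells filled with edge replicas of the
#' last frame) -> per-volume min-max normalization to \[0, 1\].
#'
#' @param segment numeric vector of exactly `round(window_s * fs)` samples.
#' @param fs sampling rate in Hz.
#' @param stft list with `n_fft` (default 256), `hop` (128) and `n_bins` (32).
#' @param window_s expected segment duration (s), default 8.
#' @return a `FeatureVolume`: list with `values` (H x W x n_bins array) and
#'   `meta` (STFT parameters, frame and padding counts).
#' @export
build_volume <- function(segment, fs, stft = list(n_fft = 256L, hop = 128L,
                                                  n_bins = 32L),
                         window_s = 8) {
  n_fft <- as.integer(stft$n_fft %||% 256L)
  hop <- as.integer(stft$hop %||% 128L)
  n_bins <- as.integer(stft$n_bins %||% 32L)
  want <- as.integer(round(window_s * fs))
  if (length(segment) != want)
    stop("shape error: segment has ", length(segment), " samples, expected ",
         want)
  L <- length(segment)
  n_frames <- (L - n_fft) %/% hop + 1L
  win <- signal::hanning(n_fft)
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- vapply(starts, function(s0) segment[(s0 + 1L):(s0 + n_fft)] * win,
                   numeric(n_fft))
  S <- Mod(stats::mvfft(frames))[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  S <- log(S + 1e-6)
  # uniform bin averaging F -> n_bins
  Fb <- nrow(S)
  bounds <- round(seq(0L, Fb, length.out = n_bins + 1L))
  red <- vapply(seq_len(n_bins), function(g)
    colMeans(S[(bounds[g] + 1L):bounds[g + 1L], , drop = FALSE]),
    numeric(n_frames))               # [T, n_bins]
  H <- as.integer(ceiling(sqrt(n_frames)))
  n_pad <- H * H - n_frames
  if (n_pad > 0L)
    red <- rbind(red, red[rep(n_frames, n_pad), , drop = FALSE])
  vol <- array(0, c(H, H, n_bins))
  for (f in seq_len(H * H)) {
    r <- (f - 1L) %/% H + 1L
    cc <- (f - 1L) %% H + 1L
    vol[r, cc, ] <- red[f, ]
  }
  rng <- range(vol)
  vol <- if (rng[2] > rng[1]) (vol - rng[1]) / (rng[2] - rng[1]) else
    array(0, dim(vol))
  structure(list(values = vol,
                 meta = list(n_fft = n_fft, hop = hop, n_bins = n_bins,
                             n_frames = n_frames, n_padded = n_pad, fs = fs,
                             grid = c(H, H))),
            class = "FeatureVolume")
}

#' @export
print.FeatureVolume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<FeatureVolume> %d x %d x %d (%d frames, %d padded)\n",
              d[1], d[2], d[3], x$meta$n_frames, x$meta$n_padded))
  invisible(x)
}

#' Pyramidal block output channels
#'
#' A pyramidal block concatenates its input (`eta` channels) with the outputs
#' of its three convolution layers (`gamma_prime` channels each), so the
#' output channel count is `gamma = eta + 3 * gamma_prime`.
#'
#' @param eta input channels (>= 1).
#' @param gamma_prime per-layer output channels (>= 1).
#' @return integer channel count.
#' @export
pyramidal_block_channels <- function(eta, gamma_prime) {
  if (any(eta < 1) || any(gamma_prime < 1))
    stop("eta and gamma_prime must be >= 1")
  as.integer(eta + 3L * gamma_prime)
}

# Kernel ladders per branch: the spectral ladder is (1,1,7),(1,1,5),(1,1,3);
# the spatial and temporal ladders mirror it on their own axes.
branch_ladders <- function() {
  list(
    spectral = list(init = c(1L, 1L, 3L),
                    ladder = list(c(1L, 1L, 7L), c(1L, 1L, 5L), c(1L, 1L, 3L))),
    spatial = list(init = c(3L, 3L, 1L),
                   ladder = list(c(3L, 3L, 1L), c(5L, 5L, 1L), c(7L, 7L, 1L))),
    temporal = list(init = c(3L, 1L, 1L),
                    ladder = list(c(7L, 1L, 1L), c(5L, 1L, 1L), c(3L, 1L, 1L))))
}

#' SST-PNet configuration
#'
#' @param n_fft,hop,n_bins STFT parameters for [build_volume()].
#' @param initial_channels channels `eta` produced by each branch's initial
#'   convolution.
#' @param gamma_prime per-layer channels of each pyramidal block.
#' @return a config list.
#' @export
sstpnet_config <- function(n_fft = 256L, hop = 128L, n_bins = 32L,
                           initial_channels = 16L, gamma_prime = 8L) {
  list(stft = list(n_fft = as.integer(n_fft), hop = as.integer(hop),
                   n_bins = as.integer(n_bins)),
       initial_channels = as.integer(initial_channels),
       gamma_prime = as.integer(gamma_prime))
}

#' Initialize SST-PNet parameters
#'
#' Bias-free convolutions (batch normalization supplies the shift) with
#' He-scaled random weights; call inside a seeded context for reproducibility.
#'
#' @param cfg an [sstpnet_config()].
#' @param in_channels input volume channels, default 1.
#' @return list with flat `params` and `state` (batch-norm running statistics).
#' @export
sstpnet_init <- function(cfg = sstpnet_config(), in_channels = 1L) {
  eta <- cfg$initial_channels
  gp <- cfg$gamma_prime
  params <- list()
  state <- list()
  for (br in names(branch_ladders())) {
    lad <- branch_ladders()[[br]]
    k <- lad$init
    params[[paste0(br, ".init.w")]] <-
      nn_init_weight(c(k, in_channels, eta), prod(k) * in_channels)
    params[[paste0(br, ".init.bn.gamma")]] <- rep(1, eta)
    params[[paste0(br, ".init.bn.beta")]] <- rep(0, eta)
    state[[paste0(br, ".init.bn.mean")]] <- rep(0, eta)
    state[[paste0(br, ".init.bn.var")]] <- rep(1, eta)
    for (l in 1:3) {
      k <- lad$ladder[[l]]
      cin <- eta + (l - 1L) * gp
      params[[paste0(br, ".l", l, ".w")]] <-
        nn_init_weight(c(k, cin, gp), prod(k) * cin)
      params[[paste0(br, ".l", l, ".bn.gamma")]] <- rep(1, gp)
      params[[paste0(br, ".l", l, ".bn.beta")]] <- rep(0, gp)
      state[[paste0(br, ".l", l, ".bn.mean")]] <- rep(0, gp)
      state[[paste0(br, ".l", l, ".bn.var")]] <- rep(1, gp)
    }
  }
  list(params = params, state = state, cfg = cfg, in_channels = in_channels)
}

#' Analytic parameter count of one pyramidal branch
#'
#' Initial convolution + three ladder layers, each `prod(kernel) * c_in *
#' c_out` weights plus `2 * c_out` batch-norm parameters.
#'
#' @param branch `"spectral"`, `"spatial"` or `"temporal"`.
#' @param eta initial channels.
#' @param gamma_prime per-layer channels.
#' @param in_channels input channels, default 1.
#' @return integer parameter count.
#' @export
sstp_branch_param_count <- function(branch, eta, gamma_prime,
                                    in_channels = 1L) {
  lad <- branch_ladders()[[match.arg(branch, names(branch_ladders()))]]
  n <- prod(lad$init) * in_channels * eta + 2L * eta
  for (l in 1:3) {
    cin <- eta + (l - 1L) * gamma_prime
    n <- n + prod(lad$ladder[[l]]) * cin * gamma_prime + 2L * gamma_prime
  }
  as.integer(n)
}

# ---- channel concat/split helpers -----------------------------------------

ch_cat <- function(xs) {
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[4L], integer(1))
  out <- array(0, c(d[1:3], sum(cs), d[5L]))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[4L]
    out[, , , (at + 1L):(at + k), ] <- x
    at <- at + k
  }
  out
}

ch_split <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(k) {
    r <- x[, , , (at + 1L):(at + k), , drop = FALSE]
    at <<- at + k
    r
  })
}

# conv (same pad, bias-free) -> BN -> Mish composite
cbm_forward <- function(x, w, gamma, beta, mean_s, var_s, training) {
  cv <- nn_conv3d_forward(x, w)
  bn <- list(gamma = gamma, beta = beta, running_mean = mean_s,
             running_var = var_s, eps = 1e-4, momentum = 0.1)
  bf <- nn_bn_forward(cv$y, bn, training)
  mf <- nn_mish_forward(bf$y)
  list(y = mf$y, cache = list(cv = cv$cache, bn = bf$cache, mi = mf$cache),
       state = bf$state)
}

cbm_backward <- function(cache, dy) {
  dz <- nn_mish_backward(cache$mi, dy)
  bb <- nn_bn_backward(cache$bn, dz)
  cb <- nn_conv3d_backward(cache$cv, bb$dx)
  list(dx = cb$dx, dw = cb$dw, dgamma = bb$dgamma, dbeta = bb$dbeta)
}

branch_forward <- function(x, params, state, branch, eta, gp, training) {
  pre <- branch
  caches <- list()
  f <- cbm_forward(x, params[[paste0(pre, ".init.w")]],
                   params[[paste0(pre, ".init.bn.gamma")]],
                   params[[paste0(pre, ".init.bn.beta")]],
                   state[[paste0(pre, ".init.bn.mean")]],
                   state[[paste0(pre, ".init.bn.var")]], training)
  caches$init <- f$cache
  new_state <- list()
  if (!is.null(f$state)) {
    new_state[[paste0(pre, ".init.bn.mean")]] <- f$state$running_mean
    new_state[[paste0(pre, ".init.bn.var")]] <- f$state$running_var
  }
  h0 <- f$y
  ys <- list()
  for (l in 1:3) {
    xin <- if (l == 1L) h0 else ch_cat(c(list(h0), ys))
    g <- cbm_forward(xin, params[[paste0(pre, ".l", l, ".w")]],
                     params[[paste0(pre, ".l", l, ".bn.gamma")]],
                     params[[paste0(pre, ".l", l, ".bn.beta")]],
                     state[[paste0(pre, ".l", l, ".bn.mean")]],
                     state[[paste0(pre, ".l", l, ".bn.var")]], training)
    caches[[paste0("l", l)]] <- g$cache
    if (!is.null(g$state)) {
      new_state[[paste0(pre, ".l", l, ".bn.mean")]] <- g$state$running_mean
      new_state[[paste0(pre, ".l", l, ".bn.var")]] <- g$state$running_var
    }
    ys[[l]] <- g$y
  }
  out <- ch_cat(c(list(h0), ys))
  list(y = out, cache = list(caches = caches, eta = eta, gp = gp),
       state = new_state)
}

branch_backward <- function(cache, dy, branch, params) {
  pre <- branch
  eta <- cache$eta; gp <- cache$gp
  parts <- ch_split(dy, c(eta, gp, gp, gp))
  dh0 <- parts[[1L]]
  dys <- parts[2:4]
  grads <- list()
  for (l in 3:1) {
    bb <- cbm_backward(cache$caches[[paste0("l", l)]], dys[[l]])
    grads[[paste0(pre, ".l", l, ".w")]] <- bb$dw
    grads[[paste0(pre, ".l", l, ".bn.gamma")]] <- bb$dgamma
    grads[[paste0(pre, ".l", l, ".bn.beta")]] <- bb$dbeta
    if (l == 1L) {
      dh0 <- dh0 + bb$dx
    } else {
      ps <- ch_split(bb$dx, c(eta, rep(gp, l - 1L)))
      dh0 <- dh0 + ps[[1L]]
      for (j in seq_len(l - 1L)) dys[[j]] <- dys[[j]] + ps[[j + 1L]]
    }
  }
  ib <- cbm_backward(cache$caches$init, dh0)
  grads[[paste0(pre, ".init.w")]] <- ib$dw
  grads[[paste0(pre, ".init.bn.gamma")]] <- ib$dgamma
  grads[[paste0(pre, ".init.bn.beta")]] <- ib$dbeta
  list(dx = ib$dx, grads = grads)
}

#' SST-PNet forward pass
#'
#' Runs the three pyramidal branches (spectral, spatial, temporal) on a
#' feature volume and concatenates their outputs along the channel axis,
#' giving `K = 3 * (eta + 3 * gamma_prime)` fused channels.  Same-size
#' padding preserves H, W and the spectral axis throughout.
#'
#' @param vol a `FeatureVolume`, a 3-D/4-D array, or a 5-D batch array
#'   \[H, W, B, C, N\].
#' @param net result of [sstpnet_init()].
#' @param training logical; batch statistics (and running-stat updates) are
#'   used when `TRUE`.
#' @return list with `beta` (5-D array \[H, W, B, K, N\]), `K`, `cache` and
#'   `state`.
#' @export
sstpnet_forward <- function(vol, net, training = FALSE) {
  x <- if (inherits(vol, "FeatureVolume")) vol$values else vol
  x <- as_batch5(x)
  eta <- net$cfg$initial_channels
  gp <- net$cfg$gamma_prime
  if (dim(x)[4L] != net$in_channels)
    stop("structural error: volume has ", dim(x)[4L],
         " channels, network expects ", net$in_channels)
  outs <- list(); caches <- list(); state <- net$state
  for (br in names(branch_ladders())) {
    f <- branch_forward(x, net$params, net$state, br, eta, gp, training)
    outs[[br]] <- f$y
    caches[[br]] <- f$cache
    for (nm in names(f$state)) state[[nm]] <- f$state[[nm]]
  }
  beta <- ch_cat(outs)
  gamma <- pyramidal_block_channels(eta, gp)
  if (dim(beta)[4L] != 3L * gamma)
    stop("structural error: fused channels ", dim(beta)[4L],
         " do not match 3 * (eta + 3 * gamma_prime) = ", 3L * gamma)
  list(beta = beta, K = 3L * gamma, cache = list(branches = caches,
                                                 gamma = gamma),
       state = state)
}

# Backward companion of sstpnet_forward
sstpnet_backward <- function(fwd, net, dbeta) {
  gamma <- fwd$cache$gamma
  parts <- ch_split(dbeta, rep(gamma, 3L))
  grads <- list()
  dx <- NULL
  brs <- names(branch_ladders())
  for (i in seq_along(brs)) {
    bb <- branch_backward(fwd$cache$branches[[brs[i]]], parts[[i]], brs[i],
                          net$params)
    grads <- grad_acc(grads, bb$grads)
    dx <- if (is.null(dx)) bb$dx else dx + bb$dx
  }
  list(dx = dx, grads = grads)
}
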