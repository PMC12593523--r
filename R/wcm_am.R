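# Tri-pattern attention (spectral / temporal / spatial coefficient maps),
# weight correction by broadcast addition and elementwise maximization, and
# the fused attention output.
#
# Position descriptors are the spectral-axis means of the feature volume; the
# spectral map is a softmax over grid positions of a dense projection of the
# per-position channel vector, the temporal map is the same computation on the
# transposed grid, and the spatial map is a softmax over feature-map index of
# a projection of each channel's global-average descriptor.

#' Initialize tri-pattern attention parameters
#'
#' Dense projections `(W_spe, b_spe)`, `(W_tem, b_tem)`, `(w_spa, b_spa)` and
#' the fusion convolution kernel of the weight-addition path.
#'
#' @param K feature-map (channel) count of the attended volume.
#' @param conv_out_channels output channels of the weight-addition Conv3D
#'   (kernel 3 x 3 x 3, same padding, bias-free).
#' @param tie_tem logical: share the temporal dense parameters with the
#'   spectral ones (used by the transpose-consistency test mode).
#' @return list with flat `params` plus the config fields.
#' @export
tpam_init <- function(K, conv_out_channels = 16L, tie_tem = FALSE) {
  params <- list(
    "att.w_spe" = stats::rnorm(K, sd = 1 / sqrt(K)),
    "att.b_spe" = 0,
    "att.w_tem" = stats::rnorm(K, sd = 1 / sqrt(K)),
    "att.b_tem" = 0,
    "att.w_spa" = stats::rnorm(1, sd = 1),
    "att.b_spa" = 0,
    "fuse.w" = nn_init_weight(c(3L, 3L, 3L, K, as.integer(conv_out_channels)),
                              27 * K))
  if (tie_tem) {
    params[["att.w_tem"]] <- params[["att.w_spe"]]
    params[["att.b_tem"]] <- params[["att.b_spe"]]
  }
  list(params = params, K = as.integer(K),
       conv_out_channels = as.integer(conv_out_channels), tie_tem = tie_tem)
}

# softmax over the first dimension of a [m, N] matrix
col_softmax <- function(m) {
  m <- sweep(m, 2L, apply(m, 2L, max))
  e <- exp(m)
  sweep(e, 2L, colSums(e), `/`)
}

# backward of col_softmax: ds = a * (da - colSums(da * a))
col_softmax_bwd <- function(a, da) {
  a * sweep(da, 2L, colSums(da * a))
}

# broadcast helpers on [H, W, K, N] targets
bc_hw <- function(a_hwn, K) {
  d <- dim(a_hwn)
  aperm(array(a_hwn, c(d[1L], d[2L], d[3L], K)), c(1L, 2L, 4L, 3L))
}
bc_k <- function(a_kn, H, W) {
  d <- dim(a_kn)
  array(rep(a_kn, each = H * W), c(H, W, d[1L], d[2L]))
}
# [H,W,K,N] -> [H,W,B,K,N]
bc_b <- function(a, B) {
  d <- dim(a)
  aperm(array(a, c(d, B)), c(1L, 2L, 5L, 3L, 4L))
}
sum_over_b <- function(x5) {
  d <- dim(x5)
  m <- aperm(x5, c(3L, 1L, 2L, 4L, 5L))
  dim(m) <- c(d[3L], prod(d[-3L]))
  s <- .colSums(m, d[3L], prod(d[-3L]))
  dim(s) <- d[-3L]
  s
}

# Attention maps for a batch: beta5 [H,W,B,K,N].
# Returns maps [H,W,N] (spe), [H,W,N] (tem, already transpose-aligned to the
# spectral grid), [K,N] (spa), with everything the backward pass needs.
att_forward <- function(beta5, params) {
  d <- dim(beta5)
  H <- d[1L]; W <- d[2L]; B <- d[3L]; K <- d[4L]; N <- d[5L]
  m <- aperm(beta5, c(3L, 1L, 2L, 4L, 5L))
  dim(m) <- c(B, H * W * K * N)
  v <- .colMeans(m, B, H * W * K * N)
  dim(v) <- c(H, W, K, N)                      # position descriptors
  vm <- aperm(v, c(1L, 2L, 4L, 3L))
  dim(vm) <- c(H * W * N, K)
  s_spe <- vm %*% params[["att.w_spe"]] + params[["att.b_spe"]]
  s_tem <- vm %*% params[["att.w_tem"]] + params[["att.b_tem"]]
  dim(s_spe) <- c(H * W, N); dim(s_tem) <- c(H * W, N)
  a_spe <- col_softmax(s_spe); dim(a_spe) <- c(H, W, N)
  a_tem <- col_softmax(s_tem); dim(a_tem) <- c(H, W, N)
  bmat <- beta5
  dim(bmat) <- c(H * W * B, K * N)
  g <- .colMeans(bmat, H * W * B, K * N)
  dim(g) <- c(K, N)                            # global-average descriptors
  s_spa <- params[["att.w_spa"]] * g + params[["att.b_spa"]]
  a_spa <- col_softmax(s_spa)                  # [K, N]
  for (nm in c("a_spe", "a_tem", "a_spa"))
    if (!all(is.finite(get(nm))))
      stop("numerical error: non-finite values in attention map ", nm)
  list(a_spe = a_spe, a_tem = a_tem, a_spa = a_spa, v = v, g = g,
       dims = d)
}

att_backward <- function(fwd, params, da_spe, da_tem, da_spa) {
  d <- fwd$dims
  H <- d[1L]; W <- d[2L]; B <- d[3L]; K <- d[4L]; N <- d[5L]
  a_spe <- fwd$a_spe; dim(a_spe) <- c(H * W, N)
  a_tem <- fwd$a_tem; dim(a_tem) <- c(H * W, N)
  dim(da_spe) <- c(H * W, N); dim(da_tem) <- c(H * W, N)
  ds_spe <- col_softmax_bwd(a_spe, da_spe)
  ds_tem <- col_softmax_bwd(a_tem, da_tem)
  ds_spa <- col_softmax_bwd(fwd$a_spa, da_spa)
  vm <- aperm(fwd$v, c(1L, 2L, 4L, 3L))
  dim(vm) <- c(H * W * N, K)
  dw_spe <- as.numeric(crossprod(vm, as.numeric(ds_spe)))
  dw_tem <- as.numeric(crossprod(vm, as.numeric(ds_tem)))
  dv_m <- outer(as.numeric(ds_spe), params[["att.w_spe"]]) +
    outer(as.numeric(ds_tem), params[["att.w_tem"]])
  dim(dv_m) <- c(H, W, N, K)
  dv <- aperm(dv_m, c(1L, 2L, 4L, 3L))        # [H,W,K,N]
  dw_spa <- sum(ds_spa * fwd$g)
  dg <- params[["att.w_spa"]] * ds_spa        # [K,N]
  dbeta <- bc_b(dv / B, B) +
    array(rep(dg / (H * W * B), each = H * W * B), d)
  grads <- list("att.w_spe" = dw_spe, "att.b_spe" = sum(ds_spe),
                "att.w_tem" = dw_tem, "att.b_tem" = sum(ds_tem),
                "att.w_spa" = dw_spa, "att.b_spa" = sum(ds_spa))
  list(dbeta = dbeta, grads = grads)
}

#' Compute the three tri-pattern attention maps
#'
#' Spectral: softmax over grid positions (i, j) of a dense projection of each
#' position's channel descriptor (spectral-axis mean).  Temporal: the same
#' computation on the transposed feature grid.  Spatial: softmax over feature
#' maps k of a projection of each channel's global-average descriptor.  Each
#' map is normalized (sums to 1); softmax uses max subtraction for stability.
#'
#' @param beta feature map: 3-D \[H, W, K\] or 4-D \[H, W, B, K\].
#' @param params attention parameters (`att.*` entries of
#'   [tpam_init()]`$params`); fresh random parameters are drawn when `NULL`.
#' @return an `AttentionMaps` object: `att_spe` (H x W), `att_tem` (W x H, on
#'   the transposed grid), `att_spa` (length K), plus the parameters used.
#' @export
compute_attention_maps <- function(beta, params = NULL) {
  d <- dim(beta)
  if (length(d) == 3L) {
    beta4 <- array(beta, c(d[1L], d[2L], 1L, d[3L]))
  } else if (length(d) == 4L) {
    beta4 <- beta
  } else stop("beta must be 3-D [H,W,K] or 4-D [H,W,B,K]")
  K <- dim(beta4)[4L]
  if (is.null(params)) params <- tpam_init(K)$params
  beta5 <- beta4
  dim(beta5) <- c(dim(beta4), 1L)
  f <- att_forward(beta5, params)
  att_spe <- f$a_spe[, , 1L]
  att_tem <- t(f$a_tem[, , 1L])     # stored on the transposed (W x H) grid
  if (is.null(dim(att_spe))) dim(att_spe) <- dim(beta4)[1:2]
  if (is.null(dim(att_tem))) dim(att_tem) <- rev(dim(beta4)[1:2])
  structure(list(att_spe = att_spe, att_tem = att_tem,
                 att_spa = as.numeric(f$a_spa[, 1L]), params = params),
            class = "AttentionMaps")
}

#' Weight correction of the attention maps
#'
#' Broadcast addition `att_add(i,j,k) = att_spe(i,j) + att_tem^T(i,j) +
#' att_spa(k)` and elementwise maximization `att_max(i,j,k) =
#' max(att_spe(i,j) * att_tem^T(i,j), att_spa(k))`, so `att_max` dominates
#' both of its constituents pointwise.
#'
#' @param maps an `AttentionMaps` object from [compute_attention_maps()].
#' @return a `CorrectedWeights` object with `att_add` and `att_max`
#'   (H x W x K arrays).
#' @export
weight_correction <- function(maps) {
  stopifnot(inherits(maps, "AttentionMaps"))
  H <- nrow(maps$att_spe); W <- ncol(maps$att_spe)
  K <- length(maps$att_spa)
  temT <- t(maps$att_tem)
  if (!all(dim(temT) == c(H, W)))
    stop("structural error: temporal map is ", nrow(maps$att_tem), " x ",
         ncol(maps$att_tem), ", cannot transpose-align to ", H, " x ", W)
  spe_k <- array(maps$att_spe, c(H, W, K))
  tem_k <- array(temT, c(H, W, K))
  spa_k <- array(rep(maps$att_spa, each = H * W), c(H, W, K))
  structure(list(att_add = spe_k + tem_k + spa_k,
                 att_max = pmax(spe_k * tem_k, spa_k)),
            class = "CorrectedWeights")
}

#' Fuse a feature map with its corrected attention weights
#'
#' `I_add = Conv3D(att_add * beta)` (3 x 3 x 3 kernel, same padding,
#' bias-free); `I_max = concat(att_max * beta, beta)` along channels;
#' `I_TPAM = maxpool(concat(I_max, I_add))` with 2 x 2 x 1 pooling, giving
#' `2K + K_add` output channels.  Pooling is skipped (with a warning) on any
#' grid axis of size 1.
#'
#' @param beta feature map, 3-D \[H, W, K\] (treated as B = 1) or 4-D
#'   \[H, W, B, K\].
#' @param cw a `CorrectedWeights` object.
#' @param conv_w fusion kernel \[3, 3, 3, K, K_add\]; `NULL` uses the identity
#'   (delta kernel, K_add = K).
#' @param pool pooling window, default `c(2, 2, 1)`.
#' @return list with `i_add`, `i_max`, `i_tpam` (4-D arrays \[H', W', B, C\]).
#' @export
tpam_fuse <- function(beta, cw, conv_w = NULL, pool = c(2L, 2L, 1L)) {
  d <- dim(beta)
  if (length(d) == 3L) beta <- array(beta, c(d[1L], d[2L], 1L, d[3L]))
  d <- dim(beta)
  H <- d[1L]; W <- d[2L]; B <- d[3L]; K <- d[4L]
  if (is.null(conv_w)) {
    conv_w <- array(0, c(1L, 1L, 1L, K, K))
    for (k in seq_len(K)) conv_w[1L, 1L, 1L, k, k] <- 1
  }
  add_b <- aperm(array(cw$att_add, c(H, W, K, B)), c(1L, 2L, 4L, 3L))
  max_b <- aperm(array(cw$att_max, c(H, W, K, B)), c(1L, 2L, 4L, 3L))
  u_add <- add_b * beta
  u5 <- u_add; dim(u5) <- c(dim(u_add), 1L)
  i_add <- nn_conv3d_forward(u5, conv_w)$y
  dim(i_add) <- dim(i_add)[1:4]
  i_max <- ch_cat(list(as_batch5(max_b * beta), as_batch5(beta)))
  z <- ch_cat(list(i_max, as_batch5(i_add)))
  if ((H == 1L && pool[1L] > 1L) || (W == 1L && pool[2L] > 1L))
    warning("grid axis of size 1: pooling skipped on that axis")
  tgt <- pool_target_dim(dim(z)[1:3], pool)
  i_tpam <- nn_maxpool3d_forward(z, target = tgt)$y
  list(i_add = i_add,
       i_max = array(i_max, dim(i_max)[1:4]),
       i_tpam = array(i_tpam, dim(i_tpam)[1:4]))
}

# ---- batched trainable TPAM (attention + correction + fusion) --------------

tpam_forward <- function(beta5, tp, training = FALSE, pool = c(2L, 2L, 1L)) {
  params <- tp$params
  d <- dim(beta5)
  H <- d[1L]; W <- d[2L]; B <- d[3L]; K <- d[4L]; N <- d[5L]
  af <- att_forward(beta5, params)
  temT <- af$a_tem                       # [H,W,N] already on the spectral grid
  # corrected weights, batched: [H,W,K,N]
  spe_k <- bc_hw(af$a_spe, K)
  tem_k <- bc_hw(temT, K)
  spa_k <- bc_k(af$a_spa, H, W)
  a_add <- spe_k + tem_k + spa_k
  pmat <- spe_k * tem_k
  a_max <- pmax(pmat, spa_k)
  msel <- pmat >= spa_k                  # product side wins ties
  u_add <- bc_b(a_add, B) * beta5
  cv <- nn_conv3d_forward(u_add, params[["fuse.w"]])
  u_max <- bc_b(a_max, B) * beta5
  z <- ch_cat(list(u_max, beta5, cv$y))
  tgt <- pool_target_dim(dim(z)[1:3], pool)
  mp <- nn_maxpool3d_forward(z, target = tgt)
  list(y = mp$y,
       cache = list(af = af, a_add = a_add, pmat = pmat, spa_k = spa_k,
                    msel = msel, beta5 = beta5, cv = cv$cache, mp = mp$cache,
                    K = K, K_add = dim(cv$y)[4L], dims = d),
       out_channels = 2L * K + dim(cv$y)[4L])
}

tpam_backward <- function(fwd, tp, dy) {
  params <- tp$params
  ca <- fwd$cache
  d <- ca$dims
  H <- d[1L]; W <- d[2L]; B <- d[3L]; K <- ca$K; N <- d[5L]
  dz <- nn_maxpool3d_backward(ca$mp, dy)
  parts <- ch_split(dz, c(K, K, ca$K_add))
  du_max <- parts[[1L]]; dbeta <- parts[[2L]]; di_add <- parts[[3L]]
  cb <- nn_conv3d_backward(ca$cv, di_add)
  du_add <- cb$dx
  a_max <- pmax(ca$pmat, ca$spa_k)
  dbeta <- dbeta + du_add * bc_b(ca$a_add, B) + du_max * bc_b(a_max, B)
  da_add <- sum_over_b(du_add * ca$beta5)     # [H,W,K,N]
  da_max <- sum_over_b(du_max * ca$beta5)
  # addition path: broadcast sums back down
  sum_k <- function(a4) {                      # [H,W,K,N] -> [H,W,N]
    m <- aperm(a4, c(3L, 1L, 2L, 4L))
    dim(m) <- c(K, H * W * N)
    s <- .colSums(m, K, H * W * N)
    dim(s) <- c(H, W, N)
    s
  }
  sum_hw <- function(a4) {                     # [H,W,K,N] -> [K,N]
    dim(a4) <- c(H * W, K * N)
    s <- .colSums(a4, H * W, K * N)
    dim(s) <- c(K, N)
    s
  }
  da_spe <- sum_k(da_add)
  da_tem <- sum_k(da_add)
  da_spa <- sum_hw(da_add)
  # maximization path
  dpmat <- da_max * ca$msel
  da_spa <- da_spa + sum_hw(da_max * !ca$msel)
  da_spe <- da_spe + sum_k(dpmat * bc_hw(ca$af$a_tem, K) / 1)
  da_tem <- da_tem + sum_k(dpmat * bc_hw(ca$af$a_spe, K) / 1)
  ab <- att_backward(ca$af, params, da_spe, da_tem, da_spa)
  dbeta <- dbeta + ab$dbeta
  grads <- ab$grads
  grads[["fuse.w"]] <- cb$dw
  if (isTRUE(tp$tie_tem)) {
    grads[["att.w_spe"]] <- grads[["att.w_spe"]] + grads[["att.w_tem"]]
    grads[["att.b_spe"]] <- grads[["att.b_spe"]] + grads[["att.b_tem"]]
    grads[["att.w_tem"]] <- NULL
    grads[["att.b_tem"]] <- NULL
  }
  list(dbeta = dbeta, grads = grads)
}
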