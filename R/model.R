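# Full model assembly: per-modality SST-PNet towers + tri-pattern attention,
# channel-wise modality fusion, then the EnDe-CNN encoder-decoder classifier
# trained with the joint cross-entropy + reconstruction objective.

#' Model configuration
#'
#' Bundles the SST-PNet, attention and EnDe-CNN settings.  `desk = TRUE`
#' selects the reduced-width configuration used for CPU-scale experiments
#' (coarser spectrogram, narrow channel widths); `desk = FALSE` gives the
#' full-width architecture defaults.
#'
#' @param desk logical, default `TRUE`.
#' @param n_classes number of output classes.
#' @param lambda_rec reconstruction-loss weight, default 0.1.
#' @param dropout detection-head dropout, default 0.3.
#' @return a `ModelConfig` list.
#' @export
model_config <- function(desk = TRUE, n_classes = 2L, lambda_rec = 0.1,
                         dropout = 0.3) {
  if (desk) {
    list(sstp = sstpnet_config(n_fft = 512L, hop = 512L, n_bins = 12L,
                               initial_channels = 2L, gamma_prime = 2L),
         conv_out_channels = 8L, pool = c(2L, 2L, 1L),
         ende = ende_config(stage_channels = c(8L, 8L, 8L), taps = 1:3,
                            dropout = dropout, n_classes = n_classes,
                            lambda_rec = lambda_rec))
  } else {
    list(sstp = sstpnet_config(),
         conv_out_channels = 16L, pool = c(2L, 2L, 1L),
         ende = ende_config(dropout = dropout, n_classes = n_classes,
                            lambda_rec = lambda_rec))
  }
}

#' Initialize the full two-modality model
#'
#' Separate SST-PNet + attention towers for ECG and PCG; their fused
#' attention outputs are concatenated channel-wise and fed to the
#' encoder-decoder classifier.
#'
#' @param vol_dim volume dims `c(H, W, B)` produced by [build_volume()] under
#'   the configured STFT settings.
#' @param cfg a [model_config()].
#' @param seed RNG seed for weight initialization.
#' @return a model object.
#' @export
model_init <- function(vol_dim, cfg = model_config(), seed = 1L) {
  with_seed(seed, {
    gamma <- pyramidal_block_channels(cfg$sstp$initial_channels,
                                      cfg$sstp$gamma_prime)
    K <- 3L * gamma
    towers <- list()
    for (m in c("ecg", "pcg")) {
      towers[[m]] <- list(sstp = sstpnet_init(cfg$sstp, in_channels = 1L),
                          tpam = tpam_init(K, cfg$conv_out_channels))
    }
    tpam_dim <- c(pool_target_dim(vol_dim[1:2], cfg$pool[1:2]), vol_dim[3L])
    fused_channels <- 2L * (2L * K + cfg$conv_out_channels)
    ende <- ende_init(tpam_dim, fused_channels, cfg$ende)
    structure(list(towers = towers, ende = ende, cfg = cfg, K = K,
                   vol_dim = as.integer(vol_dim)),
              class = "CardioModel")
  })
}

#' @export
print.CardioModel <- function(x, ...) {
  np <- sum(vapply(model_params(x), length, numeric(1)))
  cat(sprintf("<CardioModel> volume %s, K = %d per tower, %d parameters\n",
              paste(x$vol_dim, collapse = "x"), x$K, np))
  invisible(x)
}

#' Flatten all trainable parameters of a model
#'
#' @param model a `CardioModel`.
#' @return named list of numeric arrays (prefixed by component).
#' @export
model_params <- function(model) {
  out <- list()
  for (m in names(model$towers)) {
    for (nm in names(model$towers[[m]]$sstp$params))
      out[[paste0("sstp.", m, ".", nm)]] <- model$towers[[m]]$sstp$params[[nm]]
    for (nm in names(model$towers[[m]]$tpam$params))
      out[[paste0("tpam.", m, ".", nm)]] <- model$towers[[m]]$tpam$params[[nm]]
  }
  for (nm in names(model$ende$params))
    out[[paste0("ende.", nm)]] <- model$ende$params[[nm]]
  out
}

#' @noRd
model_set_params <- function(model, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (parts[1L] == "sstp") {
      key <- paste(parts[-(1:2)], collapse = ".")
      model$towers[[parts[2L]]]$sstp$params[[key]] <- flat[[nm]]
    } else if (parts[1L] == "tpam") {
      key <- paste(parts[-(1:2)], collapse = ".")
      model$towers[[parts[2L]]]$tpam$params[[key]] <- flat[[nm]]
    } else {
      key <- paste(parts[-1L], collapse = ".")
      model$ende$params[[key]] <- flat[[nm]]
    }
  }
  model
}

#' Full forward pass
#'
#' @param model a `CardioModel`.
#' @param x_ecg,x_pcg volume batches \[H, W, B, 1, N\] (3-/4-D arrays are
#'   promoted).
#' @param labels optional integer class labels (1..n_classes) enabling the
#'   loss computation.
#' @param training logical: batch-norm batch statistics and dropout active.
#' @return list with `probs` (\[n_classes, N\]), `loss`, `ce`, `rec`,
#'   latent `D`, `recon`, and caches for the backward pass.
#' @export
model_forward <- function(model, x_ecg, x_pcg, labels = NULL,
                          training = FALSE) {
  x_ecg <- as_batch5(x_ecg); x_pcg <- as_batch5(x_pcg)
  tower_out <- list(); tower_cache <- list()
  for (m in c("ecg", "pcg")) {
    x <- if (m == "ecg") x_ecg else x_pcg
    sf <- sstpnet_forward(x, model$towers[[m]]$sstp, training)
    tf <- tpam_forward(sf$beta, model$towers[[m]]$tpam, training,
                       pool = model$cfg$pool)
    tower_out[[m]] <- tf$y
    tower_cache[[m]] <- list(sf = sf, tf = tf)
  }
  fused <- ch_cat(tower_out)
  enc <- ende_encode_forward(fused, model$ende, training)
  dec <- ende_decode_forward(enc$D, model$ende, training)
  n <- dim(fused)[5L]
  flat <- matrix(enc$D, ncol = n)
  dr <- nn_dropout_forward(flat, model$ende$cfg$dropout, training)
  dn <- nn_dense_forward(dr$y, model$ende$params[["head.w"]],
                         model$ende$params[["head.b"]])
  rec <- reconstruction_loss(dec$recon, fused, k = n)
  # the training objective scales the reconstruction term per element so
  # lambda_rec is independent of the patch size; `rec` reports the patch-sum
  # definition
  patch_elems <- prod(dim(fused)[1:4])
  out <- list(logits = dn$y, probs = nn_softmax(dn$y), D = enc$D,
              recon = dec$recon, rec = rec, rec_mean = rec / patch_elems,
              cache = list(tower = tower_cache, enc = enc, dec = dec,
                           dr = dr$cache, dn = dn$cache, fused = fused,
                           labels = labels, patch_elems = patch_elems))
  if (!is.null(labels)) {
    ce <- nn_softmax_ce(dn$y, labels)
    out$ce <- ce$loss
    out$loss <- ce$loss + model$ende$cfg$lambda_rec * rec / patch_elems
    out$cache$dz <- ce$dz
  }
  out
}

#' @noRd
model_backward <- function(model, fwd) {
  ca <- fwd$cache
  n <- dim(ca$fused)[5L]
  lam <- model$ende$cfg$lambda_rec
  grads <- list()
  # detection head
  db <- nn_dense_backward(ca$dn, ca$dz)
  grads[["ende.head.w"]] <- db$dw
  grads[["ende.head.b"]] <- db$db
  dflat <- nn_dropout_backward(ca$dr, db$dx)
  dD <- array(dflat, dim = dim(fwd$D))
  # reconstruction branch: d/drecon and the flow-through-target term
  dres <- 2 * (fwd$recon - ca$fused) * (lam / (n * ca$patch_elems))
  decb <- ende_decode_backward(ca$dec, model$ende, dres)
  for (nm in names(decb$grads)) grads[[paste0("ende.", nm)]] <- decb$grads[[nm]]
  dD <- dD + decb$dD
  encb <- ende_encode_backward(ca$enc, model$ende, dD)
  grads <- grad_acc(grads, stats::setNames(encb$grads,
                                           paste0("ende.", names(encb$grads))))
  dfused <- encb$dx - dres            # target-side gradient of the L2 loss
  Ks <- rep(as.integer(2L * model$K + model$cfg$conv_out_channels),
            length(model$towers))
  parts <- ch_split(dfused, Ks)
  for (i in seq_along(names(model$towers))) {
    m <- names(model$towers)[i]
    tb <- tpam_backward(ca$tower[[m]]$tf, model$towers[[m]]$tpam, parts[[i]])
    grads <- grad_acc(grads, stats::setNames(
      tb$grads, paste0("tpam.", m, ".", names(tb$grads))))
    sb <- sstpnet_backward(ca$tower[[m]]$sf, model$towers[[m]]$sstp, tb$dbeta)
    grads <- grad_acc(grads, stats::setNames(
      sb$grads, paste0("sstp.", m, ".", names(sb$grads))))
  }
  grads
}

# Propagate updated batch-norm running statistics back into the model
#' @noRd
model_update_state <- function(model, fwd) {
  for (m in names(model$towers)) {
    st <- fwd$cache$tower[[m]]$sf$state
    for (nm in names(st)) model$towers[[m]]$sstp$state[[nm]] <- st[[nm]]
  }
  for (nm in names(fwd$cache$enc$state))
    model$ende$state[[nm]] <- fwd$cache$enc$state[[nm]]
  for (nm in names(fwd$cache$dec$state))
    model$ende$state[[nm]] <- fwd$cache$dec$state[[nm]]
  model
}
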