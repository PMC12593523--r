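test_that("attention maps are normalized and uniform for constant input", {
  # constant feature map: softmax of equal scores is uniform
  beta <- array(0.7, c(3, 4, 5))
  maps <- compute_attention_maps(beta)
  expect_equal(maps$att_spe, matrix(1 / 12, 3, 4), tolerance = 1e-12)
  expect_equal(maps$att_spa, rep(1 / 5, 5), tolerance = 1e-12)
  expect_equal(sum(maps$att_tem), 1, tolerance = 1e-12)

  set.seed(6)
  for (i in 1:20) {
    H <- sample(2:5, 1); W <- sample(2:5, 1); K <- sample(1:6, 1)
    b <- array(rnorm(H * W * 3 * K, sd = 2), c(H, W, 3, K))
    m <- compute_attention_maps(b)
    expect_lt(abs(sum(m$att_spe) - 1), 1e-6)
    expect_lt(abs(sum(m$att_tem) - 1), 1e-6)
    expect_lt(abs(sum(m$att_spa) - 1), 1e-6)
    expect_true(all(m$att_spe > 0 & m$att_spe < 1))
  }
})

test_that("spectral attention reproduces the hand-computed softmax", {
  beta <- array(c(1, 0, 0, 0), c(2, 2, 1))   # descriptors = scores
  params <- list("att.w_spe" = 1, "att.b_spe" = 0,
                 "att.w_tem" = 1, "att.b_tem" = 0,
                 "att.w_spa" = 1, "att.b_spa" = 0)
  maps <- compute_attention_maps(beta, params)
  want <- exp(c(1, 0, 0, 0)) / sum(exp(c(1, 0, 0, 0)))
  expect_equal(as.numeric(maps$att_spe), want, tolerance = 1e-4)
  expect_equal(round(as.numeric(maps$att_spe), 4),
               c(0.4754, 0.1749, 0.1749, 0.1749))
})

test_that("spatial attention is equivariant under channel permutation", {
  set.seed(7)
  beta <- array(rnorm(4 * 4 * 2 * 6), c(4, 4, 2, 6))
  params <- tpam_init(6)$params
  m1 <- compute_attention_maps(beta, params)
  perm <- sample(6)
  m2 <- compute_attention_maps(beta[, , , perm, drop = FALSE], params)
  expect_equal(m2$att_spa, m1$att_spa[perm], tolerance = 1e-12)
})

test_that("temporal attention equals spectral attention of the transposed grid", {
  set.seed(8)
  beta <- array(rnorm(3 * 5 * 2 * 4), c(3, 5, 2, 4))
  params <- tpam_init(4, tie_tem = TRUE)$params
  m1 <- compute_attention_maps(beta, params)
  bt <- aperm(beta, c(2, 1, 3, 4))
  m2 <- compute_attention_maps(bt, params)
  expect_equal(m1$att_tem, m2$att_spe, tolerance = 1e-12)
})

test_that("weight correction: broadcast addition and dominating maximum", {
  # degenerate 1x1 grid, K = 1: uniform maps are all exactly 1
  m <- structure(list(att_spe = matrix(1, 1, 1), att_tem = matrix(1, 1, 1),
                      att_spa = 1), class = "AttentionMaps")
  cw <- weight_correction(m)
  expect_equal(as.numeric(cw$att_add), 3)
  expect_equal(as.numeric(cw$att_max), 1)

  # uniform maps on a 2x2 grid with K = 2
  m <- structure(list(att_spe = matrix(0.25, 2, 2),
                      att_tem = matrix(0.25, 2, 2),
                      att_spa = c(0.5, 0.5)), class = "AttentionMaps")
  cw <- weight_correction(m)
  expect_true(all(abs(cw$att_add - 1) < 1e-12))
  expect_true(all(abs(cw$att_max - 0.5) < 1e-12))

  # dominance over random normalized maps
  set.seed(9)
  for (i in 1:20) {
    H <- sample(2:4, 1); W <- sample(2:4, 1); K <- sample(1:5, 1)
    b <- array(rnorm(H * W * 2 * K), c(H, W, 2, K))
    maps <- compute_attention_maps(b)
    cw <- weight_correction(maps)
    prod_map <- array(maps$att_spe * t(maps$att_tem), c(H, W, K))
    spa_map <- array(rep(maps$att_spa, each = H * W), c(H, W, K))
    expect_true(all(cw$att_max >= prod_map - 1e-15))
    expect_true(all(cw$att_max >= spa_map - 1e-15))
  }
})

test_that("fusion: neutral weighting, channel arithmetic, zero propagation", {
  set.seed(10)
  H <- 4; W <- 4; B <- 3; K <- 8
  beta <- array(rnorm(H * W * B * K), c(H, W, B, K))
  ones <- structure(list(att_add = array(1, c(H, W, K)),
                         att_max = array(1, c(H, W, K))),
                    class = "CorrectedWeights")
  out <- tpam_fuse(beta, ones)                   # identity convolution
  expect_equal(out$i_add, beta, tolerance = 1e-12)

  conv_w <- array(rnorm(3 * 3 * 3 * K * 8, sd = 0.1), c(3, 3, 3, K, 8))
  out <- tpam_fuse(beta, ones, conv_w)
  expect_equal(dim(out$i_max)[4], 2 * K)
  expect_equal(dim(out$i_tpam), c(2, 2, 3, 24))  # 2K + K_add; H, W halved

  zcw <- compute_attention_maps(array(0, c(H, W, B, K)))
  zout <- tpam_fuse(array(0, c(H, W, B, K)), weight_correction(zcw), conv_w)
  expect_true(all(zout$i_tpam == 0))

  expect_warning(tpam_fuse(array(1, c(1, 1, 2, 2)),
                           structure(list(att_add = array(1, c(1, 1, 2)),
                                          att_max = array(1, c(1, 1, 2))),
                                     class = "CorrectedWeights")),
                 "pooling skipped")
})

test_that("every attention parameter receives a correct nonzero gradient", {
  set.seed(11)
  beta5 <- array(rnorm(4 * 4 * 3 * 5 * 2), c(4, 4, 3, 5, 2))
  tp <- tpam_init(5, conv_out_channels = 3)
  fwd <- cp_ns$tpam_forward(beta5, tp, training = TRUE)
  tgt <- array(rnorm(length(fwd$y)), dim(fwd$y))
  bwd <- cp_ns$tpam_backward(fwd, tp, tgt)
  for (nm in c("att.w_spe", "att.w_tem", "att.w_spa", "fuse.w")) {
    g <- bwd$grads[[nm]]
    expect_true(any(g != 0), info = nm)
    loss <- function(v) {
      t2 <- tp; t2$params[[nm]] <- v
      sum(cp_ns$tpam_forward(beta5, t2, training = TRUE)$y * tgt)
    }
    idx <- seq_len(min(4, length(g)))
    expect_equal(fd_grad(loss, tp$params[[nm]], idx), g[idx],
                 tolerance = 1e-4, info = nm)
  }
})
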