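test_that("convolution output size formula matches runtime shapes", {
  expect_equal(conv_output_size(64, 0, 3, 1), 62)
  expect_equal(conv_output_size(12, 1, 3, 2), 6)
  expect_error(conv_output_size(4, 0, 7, 1), "size error")
  expect_error(conv_output_size(4, 0, 3, 0), "stride")

  set.seed(12)
  for (i in 1:30) {
    M <- sample(4:12, 3, replace = TRUE)
    k <- sample(1:3, 3, replace = TRUE)
    p <- sample(0:2, 3, replace = TRUE)
    s <- sample(1:3, 3, replace = TRUE)
    if (any(k > M + 2 * p)) next
    x <- array(rnorm(prod(M) * 2), c(M, 2, 1))
    w <- array(rnorm(prod(k) * 2 * 3), c(k, 2, 3))
    y <- cp_ns$nn_conv3d_forward(x, w, pad = p, stride = s)$y
    expect_equal(dim(y)[1:3],
                 vapply(1:3, function(j)
                   conv_output_size(M[j], p[j], k[j], s[j]), integer(1)))
  }
})

test_that("encoder taps concatenate to the expected latent", {
  set.seed(13)
  cfg <- ende_config(stage_channels = c(16L, 32L, 64L), taps = 1:3,
                     n_classes = 2)
  net <- ende_init(c(4, 4, 8), in_channels = 3, cfg = cfg)
  x <- array(rnorm(4 * 4 * 8 * 3 * 2), c(4, 4, 8, 3, 2))
  enc <- encode(x, net)
  expect_equal(dim(enc$D)[4], 112)               # 16 + 32 + 64
  expect_equal(dim(enc$D)[1:3], net$deepest)

  # stage spatial sizes follow the size formula (same-pad conv + 2x pooling)
  d <- c(4, 4, 8)
  for (l in 1:3) {
    conv_d <- vapply(d, function(m) conv_output_size(m, 1, 3, 1), integer(1))
    expect_equal(conv_d, d)                      # same padding preserves
    if (l < 3) d <- pmax(1, d %/% 2)
    expect_equal(dim(enc$stage_out[[l]])[1:3], d)
  }

  # zero input through the bias-free path gives a zero latent
  z <- encode(array(0, dim(x)), net)
  expect_true(all(z$D == 0))

  expect_error(ende_config(stage_channels = c(8, 8), taps = 1:3),
               "tap depth")
})

test_that("reconstruction loss is the mean patch squared error", {
  x <- array(rnorm(8), c(2, 2, 2, 1, 1))
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x + 1, x, k = 1), 8)
  set.seed(14)
  for (i in 1:10) {
    a <- array(rnorm(24), c(2, 2, 3, 2, 1))
    b <- array(rnorm(24), c(2, 2, 3, 2, 1))
    expect_equal(reconstruction_loss(a, b, k = 4), sum((a - b)^2) / 4,
                 tolerance = 1e-6)
  }
  expect_error(reconstruction_loss(array(0, c(2, 2)), array(0, c(2, 3))),
               "structural error")
})

test_that("decoder restores the encoder input shape, including odd axes", {
  set.seed(15)
  for (dims in list(c(4, 4, 8), c(3, 3, 5), c(6, 5, 12))) {
    cfg <- ende_config(stage_channels = c(4L, 4L, 4L), taps = 1:3,
                       n_classes = 2)
    net <- ende_init(dims, in_channels = 2, cfg = cfg)
    x <- array(rnorm(prod(dims) * 2 * 2), c(dims, 2, 2))
    enc <- encode(x, net)
    dec <- decode_and_loss(enc$D, x, net)
    expect_equal(dim(dec$recon), dim(x))
    expect_gte(dec$loss, 0)
  }
})

test_that("the detection head emits a probability simplex", {
  set.seed(16)
  cfg <- ende_config(stage_channels = c(4L, 4L, 4L), taps = 1:3,
                     n_classes = 4)
  net <- ende_init(c(4, 4, 8), in_channels = 2, cfg = cfg)
  D <- array(rnorm(prod(net$deepest) * net$latent_channels * 3),
             c(net$deepest, net$latent_channels, 3))
  p <- classify(D, net)
  expect_equal(dim(p), c(4, 3))
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  expect_error(ende_config(n_classes = 1), "n_classes")
})
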