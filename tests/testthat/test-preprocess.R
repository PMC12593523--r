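test_that("Wiener taps solve the Wiener-Hopf system", {
  # zero noise power: the identity filter is the exact solution
  expect_identical(wiener_taps(c(2, 1, 0.5, 0.2), 0), c(1, 0, 0, 0))

  # worked 2x2 system: [[2,1],[1,2]] psi = (1,1)  =>  psi = (1/3, 1/3)
  expect_equal(wiener_taps(c(2, 1), 1), c(1 / 3, 1 / 3), tolerance = 1e-12)

  # residual invariant over autocorrelations of random signals
  set.seed(11)
  for (i in 1:10) {
    x <- as.numeric(stats::arima.sim(list(ar = runif(1, -0.5, 0.9)), 3000))
    r <- cp_ns$autocorr_biased(x, 16)
    s2 <- runif(1, 0.01, 0.5) * r[1]
    psi <- wiener_taps(r, s2)
    rhs <- r; rhs[1] <- rhs[1] - s2
    expect_lt(max(abs(stats::toeplitz(r) %*% psi - rhs)), 1e-8)
  }
})

test_that("Wiener filtering is the identity when no noise is detected", {
  set.seed(2)
  x <- as.numeric(stats::filter(rnorm(2000), 0.9, method = "recursive"))
  cfg <- wiener_config(order_p = 8, noise_model = "reference_segment",
                       noise_segment = 1:100)
  x[1:100] <- 0   # flat reference: estimated noise variance is exactly zero
  y <- wiener_filter(x, cfg)
  expect_identical(as.numeric(y), x)
  expect_identical(attr(y, "taps"), c(1, rep(0, 7)))
})

test_that("Wiener filtering reduces MSE on noisy AR(1) signals", {
  # spot check here (the 100-seed sweep runs in the acceptance suite)
  set.seed(5)
  wins <- 0L
  for (s in 1:20) {
    set.seed(s)
    clean <- as.numeric(stats::filter(rnorm(20000), 0.9, method = "recursive"))
    noise <- rnorm(20000, 0, sd(clean))          # 0 dB SNR
    noisy <- clean + noise
    den <- wiener_filter(noisy, wiener_config(order_p = 32))
    if (mean((den - clean)^2) < mean((noisy - clean)^2)) wins <- wins + 1L
  }
  expect_gte(wins, 19)
})

test_that("too-short input for the Wiener filter errors", {
  expect_error(wiener_filter(rnorm(100), wiener_config(order_p = 32)),
               "too short")
})

test_that("min-max normalization maps the range exactly and is idempotent", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(2, 4, 6), 0, 10), c(0, 5, 10))
  set.seed(3)
  x <- rnorm(500)
  y <- minmax_normalize(x)
  expect_equal(range(y), c(0, 1))
  expect_equal(minmax_normalize(y), y)          # idempotence on [0, 1]
  expect_warning(z <- minmax_normalize(rep(4, 10)), "degenerate")
  expect_equal(z, rep(0, 10))
  expect_error(minmax_normalize(1:3, 1, 1), "exceed")
})

test_that("clean ECG passes false-peak elimination untouched", {
  cfg <- quick_synth_config()
  ecg <- generate_ecg(cfg, subject_seed = 9, duration_s = 30)
  out <- false_peak_elimination(ecg$samples, ecg$fs, "ECG")
  expect_equal(sum(out$peaks$is_false), 0)
  expect_identical(out$cleaned, ecg$samples)
})

test_that("injected spikes are removed and R peaks retained", {
  cfg <- synth_config(seed = 21, heart_rate_bpm = c(mean = 70, sd = 0))
  ecg <- generate_ecg(cfg, subject_seed = 21, duration_s = 30)
  x <- ecg$samples
  r <- ecg$meta$r_peaks
  # 10 spikes at 5x the QRS amplitude, placed mid-diastole (far from R peaks)
  spike_at <- (r[seq(2, 20, 2)] + round(0.55 * diff(r)[seq(2, 20, 2)]))
  amp <- 5 * max(abs(x))
  x[spike_at] <- x[spike_at] + amp
  out <- false_peak_elimination(x, ecg$fs, "ECG")
  flagged <- out$peaks$index[out$peaks$is_false]
  hit <- sum(vapply(spike_at, function(s) any(abs(flagged - s) <= 3), logical(1)))
  expect_gte(hit, 9)
  # R peaks retained: cleaned signal still carries the QRS amplitude
  kept <- sum(out$cleaned[r] > 0.5 * ecg$samples[r])
  expect_gte(kept / length(r), 0.95)
  # samples far from any flagged peak are untouched
  half <- round(0.1 * ecg$fs)
  protected <- setdiff(seq_along(x),
                       unlist(lapply(flagged, function(i)
                         max(1, i - half):min(length(x), i + half))))
  expect_identical(out$cleaned[protected], x[protected])
})

test_that("degenerate inputs to false-peak elimination are handled", {
  expect_warning(out <- false_peak_elimination(numeric(5000), 2000, "ECG"),
                 "all-zero")
  expect_identical(out$cleaned, numeric(5000))
  expect_equal(nrow(out$peaks), 0)
  # a single impulse gives < 2 candidates
  x <- numeric(5000); x[2500] <- 1
  expect_warning(out <- false_peak_elimination(x, 2000, "ECG"),
                 "fewer than 2")
  expect_identical(out$cleaned, x)
})

test_that("segment counts match the published extremes and brute force", {
  mk <- function(dur, label) signal_record(numeric(round(dur * 2000)) + 1,
                                           2000, "ECG", label = label)
  expect_equal(nrow(segment_signal(mk(35.92, "positive"))$segments), 4)
  expect_equal(nrow(segment_signal(mk(8.98, "negative"))$segments), 1)

  # brute-force enumeration of window start positions
  set.seed(8)
  for (i in 1:200) {
    fs <- 100
    dur <- runif(1, 8, 40)
    s_pos <- sample(2:10, 1); s_neg <- sample(2:10, 1)
    lab <- sample(c("positive", "negative"), 1)
    cfg <- segmentation_config(8, s_pos, s_neg)
    arc <- segment_signal(signal_record(rnorm(round(dur * fs)), fs, "ECG",
                                        label = lab), cfg)
    stride <- round((if (lab == "positive") s_pos else s_neg) * fs)
    starts <- seq(0, round(dur * fs) - 800, by = stride)
    expect_equal(nrow(arc$segments), length(starts))
    expect_equal(arc$provenance$start_sample, as.integer(starts))
  }

  expect_message(arc <- segment_signal(mk(5, "negative")), "skipped")
  expect_equal(nrow(arc$segments), 0)
})

test_that("preprocessing does not erase the class separation", {
  cfg <- quick_synth_config(n_pos = 6, n_neg = 6, seed = 31)
  coh <- generate_cohort(cfg, corrupt = TRUE)
  stat_before <- vapply(coh$records, function(p)
    murmur_band_ratio(p$pcg$samples, p$pcg$fs), numeric(1))
  stat_after <- vapply(coh$records, function(p) {
    x <- wiener_filter(p$pcg$samples, wiener_config())
    x <- suppressWarnings(false_peak_elimination(as.numeric(x), p$pcg$fs,
                                                 "PCG")$cleaned)
    murmur_band_ratio(x, p$pcg$fs)
  }, numeric(1))
  pos <- coh$manifest$label == "positive"
  auc_b <- auc_stat(stat_before, pos)
  auc_a <- auc_stat(stat_after, pos)
  expect_lt(abs(auc_a - auc_b) / auc_b, 0.1)
})
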