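test_that("ECG generator places R peaks on the RR grid deterministically", {
  cfg <- synth_config(heart_rate_bpm = c(mean = 60, sd = 0), rr_jitter_sd = 0,
                      seed = 1)
  ecg <- generate_ecg(cfg, subject_seed = 5, duration_s = 10.6)
  r <- ecg$meta$r_peaks
  expect_equal(length(r), 10)
  expect_true(all(abs(diff(r) - 2000) <= 1))
  # the sample at each ground-truth R position carries the R amplitude
  expect_true(all(ecg$samples[r] > 0.9))

  ecg2 <- generate_ecg(cfg, subject_seed = 5, duration_s = 10.6)
  expect_identical(ecg$samples, ecg2$samples)   # determinism

  # beat-frequency structure: a spectral line sits exactly at the heart rate
  # (1 Hz at 60 bpm) and the dominant line is one of its harmonics
  long <- generate_ecg(cfg, subject_seed = 6, duration_s = 60)
  spec <- Mod(stats::fft(long$samples - mean(long$samples)))
  f <- (seq_along(spec) - 1) / 60
  off_line <- mean(spec[f > 0.2 & f < 0.9 & abs(f - round(f)) > 0.1])
  expect_gt(spec[which.min(abs(f - 1))], 10 * off_line)
  band <- which(f > 0.2 & f < 30)
  fpeak <- f[band][which.max(spec[band])]
  expect_lt(abs(fpeak - round(fpeak)), 0.05)
})

test_that("PCG has S1/S2 bursts time-locked to R peaks; murmur only in positives", {
  cfg <- synth_config(heart_rate_bpm = c(mean = 60, sd = 0), rr_jitter_sd = 0,
                      seed = 2)
  ecg <- generate_ecg(cfg, subject_seed = 7, duration_s = 10.6,
                      label = "negative")
  pcg <- generate_pcg(ecg, cfg)
  env <- abs(pcg$samples)
  fs <- pcg$fs
  burst_energy <- function(t0, dur = 0.1) {
    i <- round(t0 * fs) + 1
    idx <- max(1, i - dur * fs / 2):min(length(env), i + dur * fs / 2)
    mean(env[idx]^2)
  }
  s1 <- vapply(pcg$meta$s1_times, burst_energy, numeric(1))
  s2 <- vapply(pcg$meta$s2_times[pcg$meta$s2_times < 10.5], burst_energy,
               numeric(1))
  expect_equal(length(s1), 10)
  expect_equal(length(s2), 10)
  # diastolic gaps carry far less energy than the bursts
  dia <- vapply(pcg$meta$s1_times[-1] - 0.15, burst_energy, numeric(1))
  expect_gt(min(s1), 10 * max(dia))
  expect_gt(min(s2), 3 * max(dia))

  # negative class: murmur-band inter-burst power < 10% of S1 power
  mid <- pcg$meta$s1_times[-10] + 0.22          # between S1 tail and S2
  inter <- unlist(lapply(mid, function(t0) {
    i <- round(t0 * fs) + 1; pcg$samples[i:(i + 0.06 * fs)]
  }))
  s1seg <- unlist(lapply(pcg$meta$s1_times, function(t0) {
    i <- round(t0 * fs) + 1
    pcg$samples[max(1, i - 0.05 * fs):min(length(env), i + 0.05 * fs)]
  }))
  expect_lt(mean(inter^2), 0.1 * mean(s1seg^2))

  expect_error(generate_pcg(signal_record(1:10, 10, "ECG"), cfg),
               "dependency error")
})

test_that("positive and negative cohorts separate in murmur-band power", {
  cfg <- quick_synth_config(n_pos = 15, n_neg = 15, seed = 41)
  coh <- generate_cohort(cfg)
  stat <- vapply(coh$records, function(p)
    murmur_band_ratio(p$pcg$samples, p$pcg$fs), numeric(1))
  pos <- coh$manifest$label == "positive"
  d <- (mean(stat[pos]) - mean(stat[!pos])) /
    sqrt((var(stat[pos]) + var(stat[!pos])) / 2)
  expect_gt(d, 2)
})

test_that("class separability is monotone in the murmur effect size", {
  means <- vapply(c(0.03, 0.1, 0.25), function(a) {
    cfg <- quick_synth_config(n_pos = 5, n_neg = 0, seed = 17,
                              positive_effect = list(murmur_amp = a,
                                                     murmur_band = c(120, 400),
                                                     rr_irregularity = 0))
    coh <- generate_cohort(cfg)
    mean(vapply(coh$records, function(p)
      murmur_band_ratio(p$pcg$samples, p$pcg$fs), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("corruption adds calibrated noise and Poisson spikes", {
  cfg <- quick_synth_config(seed = 3)
  ecg <- generate_ecg(cfg, subject_seed = 11, duration_s = 20)

  # all levels zero: identity
  quiet <- cfg
  quiet$noise <- list(baseline_amp = 0, baseline_band = c(0.2, 0.5),
                      powerline_amp = 0, powerline_hz = 50,
                      white_snr_db = Inf, spike_rate_hz = 0,
                      spike_amp_factor = 5)
  expect_identical(corrupt_signal(ecg, quiet)$samples, ecg$samples)

  # 0 dB white noise within +/- 0.5 dB
  wn <- quiet
  wn$noise$white_snr_db <- 0
  noisy <- corrupt_signal(ecg, wn)
  snr <- 10 * log10(mean(ecg$samples^2) /
                      mean((noisy$samples - ecg$samples)^2))
  expect_lt(abs(snr), 0.5)

  # spike counts across seeds stay inside the Poisson 99% envelope
  sp <- quiet
  sp$noise$spike_rate_hz <- 0.5
  counts <- vapply(1:40, function(s)
    length(corrupt_signal(ecg, sp, seed = s)$meta$artifacts$spikes),
    integer(1))
  lim <- stats::qpois(c(0.005, 0.995), 0.5 * 20 * 40)
  expect_gte(sum(counts), lim[1])
  expect_lte(sum(counts), lim[2])
})

test_that("cohort manifests reproduce the study's subject arithmetic", {
  # subject ratio 273:115 = 2.37 (2.4:1), and the stride rebalancing
  cfg <- synth_config(n_positive = 273, n_negative = 115, seed = 2)
  coh <- generate_cohort(cfg, signals = FALSE)
  tab <- table(coh$manifest$label)
  expect_equal(unname(tab["positive"] / tab["negative"]), 273 / 115,
               tolerance = 1e-12)
  expect_equal(round(273 / 115, 1), 2.4)
  segs <- tapply(coh$manifest$n_segments, coh$manifest$label, sum)
  ratio <- segs[["positive"]] / segs[["negative"]]
  expect_gte(ratio, 0.8)
  expect_lte(ratio, 1.25)
  # durations respect the published envelope and the 8-s window
  expect_true(all(coh$manifest$duration_s >= 9))
  expect_true(all(coh$manifest$duration_s <= 36))
  expect_equal(mean(coh$manifest$duration_s), 31.7, tolerance = 0.05)

  empty <- generate_cohort(synth_config(n_positive = 0, n_negative = 0))
  expect_equal(nrow(empty$manifest), 0)
  expect_length(empty$records, 0)
})

test_that("one seed gives a bit-identical cohort, and sidecars round trip", {
  cfg <- quick_synth_config(n_pos = 2, n_neg = 1, seed = 13)
  a <- generate_cohort(cfg, corrupt = TRUE)
  b <- generate_cohort(cfg, corrupt = TRUE)
  expect_identical(a, b)

  dir <- withr::local_tempdir()
  man_path <- write_cohort(a, dir)
  man <- utils::read.csv(man_path)
  expect_equal(nrow(man), 3)
  back <- read_record(man$pcg_path[1], "wav", modality = "PCG")
  expect_equal(length(back$samples), length(a$records[[1]]$pcg$samples))
  truth <- jsonlite::read_json(man$truth_path[1], simplifyVector = TRUE)
  expect_equal(truth$r_peaks, a$records[[1]]$ecg$meta$r_peaks)
})
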