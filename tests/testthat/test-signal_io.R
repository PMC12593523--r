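test_that("WAV round trip preserves samples within 16-bit quantization", {
  tmp <- withr::local_tempfile(fileext = ".wav")
  # container metadata passthrough on a trivial file
  zero <- signal_record(numeric(2000) + 0, fs = 2000, modality = "PCG")
  write_wav(zero, tmp)
  back <- read_record(tmp, "wav", modality = "PCG")
  expect_length(back$samples, 2000)
  expect_equal(back$fs, 2000)
  expect_true(all(back$samples == 0))

  cfg <- quick_synth_config()
  ecg <- generate_ecg(cfg, subject_seed = 3, duration_s = 4)
  scaled <- signal_record(ecg$samples / max(abs(ecg$samples)) * 0.9,
                          fs = ecg$fs, modality = "ECG")
  write_wav(scaled, tmp)
  back <- read_record(tmp, "wav", modality = "ECG")
  expect_equal(length(back$samples), length(scaled$samples))
  expect_lt(max(abs(back$samples - scaled$samples)), 2^-15)
})

test_that("CSV dialect: rate from median step, jitter and order rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "0,0.1", "0.0005,0.2", "0.001,0.3"), tmp)
  rec <- read_record(tmp, "csv", modality = "ECG")
  expect_length(rec$samples, 3)
  expect_equal(rec$fs, 2000)

  # headerless dialect is accepted too
  writeLines(c("0,0.1", "0.001,0.2", "0.002,0.3"), tmp)
  expect_equal(read_record(tmp, "csv", modality = "ECG")$fs, 1000)

  writeLines(c("time_s,value", "0,0.1", "0.0005,0.2", "0.0012,0.3"), tmp)
  expect_error(read_record(tmp, "csv", modality = "ECG"), "jitter")

  writeLines(c("time_s,value", "0,0.1", "0.002,0.2", "0.001,0.3"), tmp)
  expect_error(read_record(tmp, "csv", modality = "ECG"),
               "not strictly increasing")

  rec <- signal_record(sin(1:100), fs = 500, modality = "ECG")
  write_signal_csv(rec, tmp)
  back <- read_record(tmp, "csv", modality = "ECG")
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$fs, 500)
})

test_that("WFDB records are read with gain and baseline applied", {
  dir <- withr::local_tempdir()
  adc <- as.integer(round(sin(2 * pi * 5 * (0:999) / 250) * 400) + 100L)
  writeBin(adc, file.path(dir, "rec01.dat"), size = 2L, endian = "little")
  writeLines(c("rec01 1 250 1000", "rec01.dat 16 200(100)/mV 12 0 0 0 0 II"),
             file.path(dir, "rec01.hea"))
  rec <- read_record(file.path(dir, "rec01.hea"), "wfdb", modality = "ECG")
  expect_equal(rec$fs, 250)
  expect_length(rec$samples, 1000)
  expect_equal(rec$samples, (adc - 100) / 200, tolerance = 1e-12)
})

test_that("resampling: identity, length scaling, band preservation", {
  rec <- signal_record(make_tone(50, 2000, 2), 2000, "ECG")
  expect_identical(resample_record(rec, 2000), rec)

  rec1k <- signal_record(make_bandlimited(8000, 1000), 1000, "ECG")
  up <- resample_record(rec1k, 2000)
  expect_equal(length(up$samples), 16000, tolerance = 1)
  expect_equal(up$fs, 2000)

  tone <- signal_record(make_tone(50, 4000, 4), 4000, "PCG")
  down <- resample_record(tone, 2000)
  spec <- Mod(stats::fft(down$samples))[1:(length(down$samples) %/% 2)]
  f_axis <- (seq_along(spec) - 1) * 2000 / length(down$samples)
  expect_equal(f_axis[which.max(spec)], 50, tolerance = 0.2)

  expect_error(resample_record(rec, -1), "target_fs")
})

test_that("down-up resampling of band-limited signals is near lossless", {
  for (seed in 1:3) {
    # band-limited below 0.4x the LOWER rate of the down-up pair
    x <- make_bandlimited(16000, 2000, max_frac = 0.19, seed = seed)
    rec <- signal_record(x, 2000, "ECG")
    back <- resample_record(resample_record(rec, 1000), 2000)
    rel <- sqrt(mean((back$samples - x)^2)) / sqrt(mean(x^2))
    expect_lt(rel, 1e-3)
  }
})

test_that("segment archives round trip exactly through HDF5", {
  tmp <- withr::local_tempfile(fileext = ".h5")
  empty <- segment_archive(matrix(numeric(), 0, 16000), fs = 2000, window_s = 8)
  write_archive(empty, tmp)
  back <- read_archive(tmp)
  expect_equal(nrow(back$segments), 0)
  expect_equal(back$fs, 2000)
  expect_equal(back$window_s, 8)

  set.seed(4)
  segs <- matrix(rnorm(3 * 16000), 3, 16000)
  arc <- segment_archive(segs, 2000, 8, labels = c("positive", "negative", "positive"),
                         provenance = data.frame(record_id = c("a", "a", "b"),
                                                 start_sample = c(0L, 16000L, 0L)))
  write_archive(arc, tmp)
  back <- read_archive(tmp)
  expect_identical(back$segments, arc$segments)   # bit-exact float64
  expect_identical(back$labels, arc$labels)
  expect_identical(back$provenance$start_sample, arc$provenance$start_sample)

  # invariant violations
  expect_error(segment_archive(matrix(0, 2, 15999), 2000, 8,
                               labels = c("a", "b")),
               "invariant")
  expect_error(segment_archive(segs, 2000, 8, labels = "positive"),
               "invariant")

  # corrupt archive: a file without the fs/window attributes
  bad <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(bad)
  rhdf5::h5write(segs, bad, "segments")
  expect_error(read_archive(bad), "corrupt")
})
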