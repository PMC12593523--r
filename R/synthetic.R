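# Deterministic synthetic ECG/PCG cohort generator.
#
# The generator emulates the study conditions every downstream stage is
# exercised under: quasi-periodic Gaussian-template ECG with P/QRS/T
# morphology, PCG with S1/S2 bursts time-locked to the R peaks, a band-limited
# systolic murmur for the positive class, and controllable baseline wander,
# powerline interference, white noise and spike artifacts.

#' Synthetic cohort configuration
#'
#' Defaults reflect the target recording population: recording durations
#' lognormal with mean about 31.7 s clipped to \[9, 36\] s, subject heart
#' rates 70 +/- 7 bpm, and a 120-400 Hz systolic murmur as the positive-class
#' effect.
#'
#' @param n_positive,n_negative subject counts per class.
#' @param fs sampling rate in Hz, default 2000.
#' @param duration_dist list with `meanlog`, `sdlog`, `min`, `max` for the
#'   clipped lognormal duration distribution (seconds).
#' @param heart_rate_bpm length-2 vector `c(mean, sd)` of subject heart rates.
#' @param rr_jitter_sd within-subject RR-interval jitter, as a fraction of the
#'   mean RR interval.
#' @param ecg_morphology data frame of Gaussian wave components with columns
#'   `wave`, `amplitude` (mV), `width` (s), `offset` (s relative to R).
#' @param pcg_s1_s2 list of S1/S2 burst parameters: centre frequency (Hz),
#'   duration (s), amplitude, and the S2 placement fraction of the RR
#'   interval.
#' @param positive_effect list: `murmur_amp` (murmur amplitude relative to
#'   S1), `murmur_band` (Hz), optional `rr_irregularity` (extra RR jitter
#'   fraction for positive subjects).
#' @param noise list of corruption levels: `baseline_amp` and `baseline_band`
#'   (Hz), `powerline_amp` and `powerline_hz`, `white_snr_db` (`Inf` for
#'   none), `spike_rate_hz`, `spike_amp_factor` (times the clean signal's
#'   maximum).
#' @param seed RNG seed (R's default Mersenne-Twister; one seed gives a
#'   bit-identical cohort).
#' @return a `SynthConfig` list.
#' @export
synth_config <- function(n_positive = 10L, n_negative = 10L, fs = 2000,
                         duration_dist = list(meanlog = log(32.5),
                                              sdlog = 0.18, min = 9, max = 36),
                         heart_rate_bpm = c(mean = 70, sd = 7),
                         rr_jitter_sd = 0.03,
                         ecg_morphology = default_ecg_morphology(),
                         pcg_s1_s2 = list(s1_freq = 80, s1_dur = 0.10,
                                          s1_amp = 1.0, s2_freq = 120,
                                          s2_dur = 0.08, s2_amp = 0.8,
                                          s2_frac = 0.35),
                         positive_effect = list(murmur_amp = 0.25,
                                                murmur_band = c(120, 400),
                                                rr_irregularity = 0),
                         noise = list(baseline_amp = 0.1,
                                      baseline_band = c(0.2, 0.5),
                                      powerline_amp = 0.05, powerline_hz = 50,
                                      white_snr_db = 20,
                                      spike_rate_hz = 0.1,
                                      spike_amp_factor = 5),
                         seed = 1L) {
  stopifnot(n_positive >= 0, n_negative >= 0, fs > 0,
            duration_dist$min >= 8, duration_dist$max > duration_dist$min)
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative), fs = fs,
                 duration_dist = duration_dist,
                 heart_rate_bpm = heart_rate_bpm,
                 rr_jitter_sd = rr_jitter_sd,
                 ecg_morphology = ecg_morphology, pcg_s1_s2 = pcg_s1_s2,
                 positive_effect = positive_effect, noise = noise,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Default Gaussian ECG wave morphology
#'
#' Textbook-scale P/Q/R/S/T amplitudes (mV), widths and offsets from the R
#' peak (s).
#'
#' @return data frame with columns `wave`, `amplitude`, `width`, `offset`.
#' @export
default_ecg_morphology <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.12, -0.10, 1.00, -0.15, 0.30),
    width = c(0.025, 0.010, 0.012, 0.010, 0.060),
    offset = c(-0.18, -0.035, 0.00, 0.035, 0.30))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

draw_duration <- function(cfg) {
  d <- stats::rlnorm(1, cfg$duration_dist$meanlog, cfg$duration_dist$sdlog)
  min(max(d, cfg$duration_dist$min), cfg$duration_dist$max)
}

# RR sequence (s) covering at least `duration` seconds
draw_rr <- function(cfg, duration, label) {
  hr <- stats::rnorm(1, cfg$heart_rate_bpm[["mean"]], cfg$heart_rate_bpm[["sd"]])
  hr <- min(max(hr, 40), 140)
  rr0 <- 60 / hr
  jit <- cfg$rr_jitter_sd
  if (is_positive_label(label))
    jit <- jit + (cfg$positive_effect$rr_irregularity %||% 0)
  n <- ceiling(duration / rr0) + 5L
  rr <- rr0 * pmax(0.5, 1 + stats::rnorm(n, 0, jit))
  rr
}

#' Generate one synthetic ECG record
#'
#' A sum of per-beat Gaussian components placed on an RR sequence with
#' Gaussian jitter.  Ground-truth R-peak sample positions are stored in
#' `meta$r_peaks`; the RR sequence in `meta$rr`.
#'
#' @param cfg a [synth_config()].
#' @param subject_seed integer seed for this subject.
#' @param duration_s optional fixed duration (drawn from `duration_dist` when
#'   `NULL`).
#' @param label class label for the record.
#' @param record_id identifier.
#' @return a clean `SignalRecord` (modality ECG).
#' @export
generate_ecg <- function(cfg = synth_config(), subject_seed = cfg$seed,
                         duration_s = NULL, label = "negative",
                         record_id = "ecg") {
  with_seed(subject_seed, {
    if (is.null(duration_s)) duration_s <- draw_duration(cfg)
    rr <- draw_rr(cfg, duration_s, label)
    n <- as.integer(round(duration_s * cfg$fs))
    t <- (seq_len(n) - 1L) / cfg$fs
    r_times <- cumsum(rr)
    r_times <- r_times[r_times < duration_s - 0.05]
    x <- numeric(n)
    mor <- cfg$ecg_morphology
    for (k in seq_len(nrow(mor))) {
      a <- mor$amplitude[k]; s <- mor$width[k]; off <- mor$offset[k]
      for (tc in r_times + off) {
        lo <- max(1L, as.integer(floor((tc - 4 * s) * cfg$fs)) + 1L)
        hi <- min(n, as.integer(ceiling((tc + 4 * s) * cfg$fs)) + 1L)
        if (hi < lo) next
        idx <- lo:hi
        x[idx] <- x[idx] + a * exp(-((t[idx] - tc)^2) / (2 * s^2))
      }
    }
    r_peaks <- as.integer(round(r_times * cfg$fs)) + 1L
    r_peaks <- r_peaks[r_peaks >= 1L & r_peaks <= n]
    signal_record(x, cfg$fs, modality = "ECG", label = label,
                  record_id = record_id,
                  meta = list(r_peaks = r_peaks, rr = rr,
                              duration_s = duration_s,
                              subject_seed = subject_seed))
  })
}

gauss_burst <- function(t, center, dur, freq, amp, phase = 0) {
  s <- dur / 6
  amp * exp(-((t - center)^2) / (2 * s^2)) * sin(2 * pi * freq * (t - center) + phase)
}

# White noise band-passed with a hard FFT mask
bandlimited_noise <- function(n, fs, band) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  Z[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(Z, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate the PCG paired to an ECG record
#'
#' Places an S1 burst (modulated sinusoid) at every ground-truth R peak and an
#' S2 burst at `R + s2_frac * RR`.  For positive-class records a band-limited
#' (120-400 Hz by default) murmur is added between S1 and S2 at the
#' configured relative amplitude.
#'
#' @param ecg_rec ECG `SignalRecord` carrying `meta$r_peaks` ground truth.
#' @param cfg a [synth_config()].
#' @param record_id identifier.
#' @return a clean `SignalRecord` (modality PCG) whose label matches the ECG.
#' @export
generate_pcg <- function(ecg_rec, cfg = synth_config(), record_id = NULL) {
  if (is.null(ecg_rec$meta$r_peaks))
    stop("dependency error: ECG record lacks R-peak ground truth metadata")
  if (is.null(record_id)) record_id <- sub("ecg", "pcg", ecg_rec$record_id)
  seed <- (ecg_rec$meta$subject_seed %||% cfg$seed) + 7919L
  with_seed(seed, {
    fs <- ecg_rec$fs
    n <- length(ecg_rec$samples)
    t <- (seq_len(n) - 1L) / fs
    p <- cfg$pcg_s1_s2
    r_t <- (ecg_rec$meta$r_peaks - 1L) / fs
    rr_local <- if (length(r_t) >= 2L) {
      d <- diff(r_t); c(d, d[length(d)])
    } else rep(0.8, length(r_t))
    x <- numeric(n)
    s1_t <- r_t
    s2_t <- r_t + p$s2_frac * rr_local
    for (i in seq_along(r_t)) {
      x <- x + gauss_burst(t, s1_t[i], p$s1_dur, p$s1_freq, p$s1_amp,
                           phase = stats::runif(1, 0, 2 * pi))
      if (s2_t[i] < t[n])
        x <- x + gauss_burst(t, s2_t[i], p$s2_dur, p$s2_freq, p$s2_amp,
                             phase = stats::runif(1, 0, 2 * pi))
    }
    if (is_positive_label(ecg_rec$label) && cfg$positive_effect$murmur_amp > 0) {
      mur <- bandlimited_noise(n, fs, cfg$positive_effect$murmur_band) *
        cfg$positive_effect$murmur_amp * p$s1_amp
      env <- numeric(n)
      for (i in seq_along(r_t)) {
        a <- s1_t[i] + p$s1_dur / 2
        b <- s2_t[i] - p$s2_dur / 2
        if (b <= a) next
        idx <- which(t >= a & t <= b)
        if (length(idx))
          env[idx] <- pmax(env[idx], sin(pi * (t[idx] - a) / (b - a)))
      }
      x <- x + mur * env
    }
    signal_record(x, fs, modality = "PCG", label = ecg_rec$label,
                  record_id = record_id,
                  meta = list(r_peaks = ecg_rec$meta$r_peaks,
                              s1_times = s1_t, s2_times = s2_t,
                              subject_seed = seed))
  })
}

#' Corrupt a record with realistic noise and spike artifacts
#'
#' Adds baseline wander (a low-frequency sinusoid), powerline interference,
#' white noise at a prescribed SNR, and Poisson-placed spike artifacts whose
#' ground-truth positions are stored in `meta$artifacts`.  With all levels
#' zero (and `white_snr_db = Inf`) the record is returned unchanged.
#'
#' @param rec a `SignalRecord`.
#' @param cfg a [synth_config()]; the `noise` block controls the levels.
#' @param seed RNG seed; defaults to the record's subject seed + 104729.
#' @return the corrupted `SignalRecord`.
#' @export
corrupt_signal <- function(rec, cfg = synth_config(), seed = NULL) {
  nz <- cfg$noise
  if (is.null(seed)) seed <- (rec$meta$subject_seed %||% cfg$seed) + 104729L
  with_seed(seed, {
    x <- rec$samples
    n <- length(x)
    fs <- rec$fs
    t <- (seq_len(n) - 1L) / fs
    if (nz$baseline_amp > 0) {
      f_bw <- stats::runif(1, nz$baseline_band[1], nz$baseline_band[2])
      x <- x + nz$baseline_amp * sin(2 * pi * f_bw * t + stats::runif(1, 0, 2 * pi))
    }
    if (nz$powerline_amp > 0)
      x <- x + nz$powerline_amp * sin(2 * pi * nz$powerline_hz * t)
    if (is.finite(nz$white_snr_db)) {
      psig <- mean(rec$samples^2)
      sdn <- sqrt(psig * 10^(-nz$white_snr_db / 10))
      x <- x + stats::rnorm(n, 0, sdn)
    }
    spikes <- integer()
    if (nz$spike_rate_hz > 0) {
      k <- stats::rpois(1, nz$spike_rate_hz * n / fs)
      if (k > 0) {
        spikes <- sort(sample.int(n, min(k, n)))
        amp <- nz$spike_amp_factor * max(abs(rec$samples))
        x[spikes] <- x[spikes] + amp * sample(c(-1, 1), length(spikes),
                                              replace = TRUE)
      }
    }
    meta <- rec$meta
    meta$artifacts <- list(spikes = spikes)
    signal_record(x, fs, modality = rec$modality, label = rec$label,
                  record_id = rec$record_id, meta = meta)
  })
}

#' Generate a labeled paired ECG/PCG cohort
#'
#' Draws `n_positive + n_negative` subjects with durations from the clipped
#' lognormal distribution, generates the paired clean records, optionally
#' corrupts them, and returns them with a manifest.
#'
#' @param cfg a [synth_config()].
#' @param corrupt logical: apply [corrupt_signal()] to both modalities.
#' @param signals logical: synthesize the waveforms (`TRUE`), or draw only
#'   the per-subject durations and produce the manifest (`FALSE`; the
#'   durations are identical to a full run with the same seed).
#' @return list with `records` (list of `list(ecg =, pcg =)` pairs; `NULL`s
#'   when `signals = FALSE`) and `manifest` (data frame: `record_id`,
#'   `label`, `duration_s`, `n_segments` under the default segmentation).
#' @export
generate_cohort <- function(cfg = synth_config(), corrupt = FALSE,
                            signals = TRUE) {
  n_tot <- cfg$n_positive + cfg$n_negative
  labels <- rep(c("positive", "negative"), c(cfg$n_positive, cfg$n_negative))
  records <- vector("list", n_tot)
  manifest <- data.frame(record_id = character(n_tot), label = labels,
                         duration_s = numeric(n_tot),
                         n_segments = integer(n_tot),
                         stringsAsFactors = FALSE)
  segcfg <- segmentation_config()
  for (i in seq_len(n_tot)) {
    sseed <- cfg$seed + i * 1000L
    id <- sprintf("s%04d", i)
    if (signals) {
      ecg <- generate_ecg(cfg, subject_seed = sseed, label = labels[i],
                          record_id = paste0(id, "_ecg"))
      pcg <- generate_pcg(ecg, cfg, record_id = paste0(id, "_pcg"))
      if (corrupt) {
        ecg <- corrupt_signal(ecg, cfg)
        pcg <- corrupt_signal(pcg, cfg)
      }
      records[[i]] <- list(ecg = ecg, pcg = pcg)
      dur <- ecg$meta$duration_s
      L <- length(ecg$samples)
    } else {
      dur <- with_seed(sseed, draw_duration(cfg))
      L <- as.integer(round(dur * cfg$fs))
    }
    w <- round(segcfg$window_s * cfg$fs)
    s <- round((if (is_positive_label(labels[i])) segcfg$stride_positive_s
                else segcfg$stride_negative_s) * cfg$fs)
    manifest$record_id[i] <- id
    manifest$duration_s[i] <- dur
    manifest$n_segments[i] <- if (L < w) 0L else (L - w) %/% s + 1L
  }
  list(records = records, manifest = manifest)
}

#' Write a cohort to disk
#'
#' PCG as 16-bit WAV, ECG as CSV, ground truth (R peaks, artifact positions)
#' as JSON sidecars, plus a manifest CSV.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$ecg_path <- file.path(dir, paste0(man$record_id, "_ecg.csv"))
  man$pcg_path <- file.path(dir, paste0(man$record_id, "_pcg.wav"))
  man$truth_path <- file.path(dir, paste0(man$record_id, "_truth.json"))
  for (i in seq_len(nrow(man))) {
    pair <- cohort$records[[i]]
    write_signal_csv(pair$ecg, man$ecg_path[i])
    write_wav(pair$pcg, man$pcg_path[i])
    jsonlite::write_json(list(r_peaks = pair$ecg$meta$r_peaks,
                              artifacts = pair$ecg$meta$artifacts %||% list()),
                         man$truth_path[i], auto_unbox = TRUE)
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Murmur-band power ratio
#'
#' Fraction of total spectral power inside the murmur band (120-400 Hz by
#' default): the scale-invariant statistic that separates the synthetic
#' classes.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band frequency band in Hz.
#' @return scalar in \[0, 1\].
#' @export
murmur_band_ratio <- function(x, fs, band = c(120, 400)) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2
  half <- seq_len(n %/% 2L + 1L)
  f <- (half - 1L) * fs / n
  P <- P[half]
  s <- sum(P)
  if (s <= 0) return(0)
  sum(P[f >= band[1] & f <= band[2]]) / s
}
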