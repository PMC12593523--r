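# Denoising, normalization, false-peak elimination and segmentation.

#' Wiener filter configuration
#'
#' @param order_p number of filter taps (>= 1), default 32.
#' @param noise_model `"white_mad"` (white-noise variance from the
#'   median-absolute-deviation of first differences) or `"reference_segment"`
#'   (variance of a user-marked noise-only stretch).
#' @param frame_len samples per frame for local autocorrelation estimation;
#'   0 uses the whole signal.  Must be 0 or >= 4 * `order_p`.
#' @param noise_segment index range (integer vector) of a noise-only stretch,
#'   required for `noise_model = "reference_segment"`.
#' @return a `WienerConfig` list.
#' @export
wiener_config <- function(order_p = 32L, noise_model = c("white_mad",
                                                         "reference_segment"),
                          frame_len = 0L, noise_segment = NULL) {
  noise_model <- match.arg(noise_model)
  order_p <- as.integer(order_p)
  if (order_p < 1L) stop("order_p must be >= 1")
  if (frame_len != 0L && frame_len < 4L * order_p)
    stop("frame_len must be 0 or >= 4 * order_p")
  structure(list(order_p = order_p, noise_model = noise_model,
                 frame_len = as.integer(frame_len),
                 noise_segment = noise_segment),
            class = "WienerConfig")
}

# Biased autocorrelation r_xx(0..p-1) = sum x(n) x(n+k) / n, via FFT.
autocorr_biased <- function(x, p) {
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  r <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / nfft
  r[seq_len(p)] / n
}

# Raw (unscaled) median absolute deviation
mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

#' Estimate white-noise variance from first differences
#'
#' `sigma^2 = (MAD(diff(x)) / (sqrt(2) * 0.6745))^2`: differencing doubles the
#' white-noise variance while largely cancelling the smooth signal, and the
#' MAD makes the estimate robust to QRS/heart-sound transients.
#'
#' @param x numeric signal.
#' @return estimated noise variance.
#' @export
estimate_noise_variance <- function(x) {
  (mad_raw(diff(x)) / (sqrt(2) * 0.6745))^2
}

#' Wiener-Hopf optimal taps
#'
#' Solves the p x p Toeplitz system `R_xx Psi = r_xrho` for the optimal filter
#' taps, where `r_xrho(k) = r_xx(k) - sigma2 * [k == 0]` under the
#' additive-uncorrelated-white-noise model.  If `sigma2` is zero the exact
#' algebraic solution `Psi = e0` (identity filter) is returned.  An
#' ill-conditioned system (condition number > 1e12) is ridge-regularized with
#' `1e-8 * r_xx(0)` on the diagonal, with a warning.
#'
#' @param r_xx autocorrelation values at lags 0..p-1.
#' @param sigma2 noise variance at lag 0.
#' @return numeric vector of p taps.
#' @export
wiener_taps <- function(r_xx, sigma2) {
  p <- length(r_xx)
  if (sigma2 <= 0) return(c(1, numeric(p - 1L)))
  R <- stats::toeplitz(r_xx)
  r <- r_xx
  r[1L] <- r[1L] - sigma2
  if (kappa(R, exact = FALSE) > 1e12) {
    warning("ill-conditioned Wiener-Hopf system; applying ridge 1e-8 * r_xx(0)")
    R <- R + diag(1e-8 * r_xx[1L], p)
  }
  as.numeric(solve(R, r))
}

#' Wiener-filter denoising
#'
#' Finite-impulse-response Wiener filter: the output is
#' `lambda(n) = sum_k Psi_k x(n - k)` with taps from [wiener_taps()], using a
#' zero-padded history so the output length equals the input length.  The
#' noise spectrum is modelled as white with variance estimated by
#' [estimate_noise_variance()] (or from a marked noise-only segment); the
#' autocorrelation is estimated from the whole signal, or averaged over frames
#' of `frame_len` samples when requested.
#'
#' @param x numeric signal (length > 4 * `order_p`).
#' @param cfg a [wiener_config()].
#' @return denoised signal of the same length; the taps and estimated noise
#'   variance are attached as attributes `taps` and `sigma2`.
#' @export
wiener_filter <- function(x, cfg = wiener_config()) {
  p <- cfg$order_p
  if (length(x) <= 4L * p)
    stop("input too short: need more than ", 4L * p, " samples for order ", p)
  sigma2 <- switch(cfg$noise_model,
    white_mad = estimate_noise_variance(x),
    reference_segment = {
      if (is.null(cfg$noise_segment))
        stop("reference_segment noise model needs cfg$noise_segment")
      stats::var(x[cfg$noise_segment])
    })
  if (cfg$frame_len > 0L) {
    starts <- seq(1L, length(x) - cfg$frame_len + 1L, by = cfg$frame_len)
    acc <- Reduce(`+`, lapply(starts, function(s)
      autocorr_biased(x[s:(s + cfg$frame_len - 1L)], p)))
    r_xx <- acc / length(starts)
  } else {
    r_xx <- autocorr_biased(x, p)
  }
  taps <- wiener_taps(r_xx, sigma2)
  if (sigma2 <= 0) {
    y <- x
  } else {
    y <- as.numeric(signal::filter(taps, 1, x))  # FIR, zero initial state
  }
  attr(y, "taps") <- taps
  attr(y, "sigma2") <- sigma2
  y
}

#' Min-max normalization
#'
#' Linear rescaling `(x - min) / (max - min) * (new_max - new_min) + new_min`,
#' so the observed minimum maps exactly to `new_min` and the maximum to
#' `new_max`.  Constant input (degenerate range) returns `new_min` everywhere
#' with a warning.
#'
#' @param x numeric vector (length >= 1).
#' @param new_min,new_max target range bounds, default \[0, 1\];
#'   `new_max > new_min` required.
#' @return rescaled numeric vector.
#' @export
minmax_normalize <- function(x, new_min = 0, new_max = 1) {
  if (new_max <= new_min) stop("new_max must exceed new_min")
  if (length(x) < 1L) stop("empty input")
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    warning("degenerate range (constant input): returning new_min everywhere")
    return(rep(new_min, length(x)))
  }
  (x - lo) / (hi - lo) * (new_max - new_min) + new_min
}

# ---- false-peak elimination ------------------------------------------------

#' False-peak elimination configuration
#'
#' Cutoffs for the per-peak anomaly features and the voting rule.  A candidate
#' peak is flagged false when at least `votes` features exceed their cutoffs.
#'
#' @param c threshold constant: the adaptive amplitude threshold is
#'   `median_w(|x|) + c * MAD_w(|x|)` in sliding windows of `window_s` seconds.
#' @param window_s sliding-window length for the adaptive threshold (s).
#' @param z_cutoff robust z-score cutoff for interval, amplitude, local
#'   variance and skewness features.
#' @param kurtosis_cutoff excess-kurtosis cutoff for the +/-100 ms window.
#' @param ratio_cutoff out-of-band power-fraction cutoff.
#' @param votes number of exceeded cutoffs required to flag a peak.
#' @param refractory_s minimum separation between candidate peaks (s); within
#'   a conflict the larger peak wins.  The 0.35 s default merges sub-dominant
#'   waves of the same beat (P/T, or S2 with S1) into the dominant peak while
#'   keeping successive beats separate up to about 170 bpm.
#' @param local_s half-width of the local feature window (s).
#' @return an `FpeConfig` list.
#' @export
fpe_config <- function(c = 4, window_s = 2, z_cutoff = 3, kurtosis_cutoff = 8,
                       ratio_cutoff = 0.5, votes = 2L, refractory_s = 0.35,
                       local_s = 0.1) {
  structure(list(c = c, window_s = window_s, z_cutoff = z_cutoff,
                 kurtosis_cutoff = kurtosis_cutoff,
                 ratio_cutoff = ratio_cutoff, votes = as.integer(votes),
                 refractory_s = refractory_s, local_s = local_s),
            class = "FpeConfig")
}

# Robust z-scores with a relative floor on the spread: when the MAD falls
# below 5% of the median magnitude, spread that small is physiologically
# negligible and would otherwise inflate z-scores of perfectly regular beats.
robust_z <- function(v) {
  med <- stats::median(v)
  s <- 1.4826 * mad_raw(v)
  s <- max(s, 0.05 * abs(med), 1e-12)
  (v - med) / s
}

# Sliding-window median and MAD of |x| via running medians
adaptive_threshold <- function(ax, fs, window_s, c) {
  k <- as.integer(round(window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(ax) %% 2L == 0L) length(ax) - 1L else length(ax))
  med <- stats::runmed(ax, k, endrule = "median")
  madw <- stats::runmed(abs(ax - med), k, endrule = "median")
  med + c * madw
}

physio_band <- function(modality) {
  if (modality == "ECG") c(0.5, 40) else c(25, 400)
}

# Fraction of spectral power outside [lo, hi] for a short window
out_of_band_ratio <- function(w, fs, band) {
  n <- length(w)
  w <- w - mean(w)
  P <- Mod(stats::fft(w))^2
  half <- seq_len(n %/% 2L + 1L)
  f <- (half - 1L) * fs / n
  P <- P[half]
  tot <- sum(P)
  if (tot <= 0) return(0)
  sum(P[f < band[1] | f > band[2]]) / tot
}

#' Detect and remove false peaks
#'
#' Candidate peaks are local maxima of `|x|` above the adaptive amplitude
#' threshold `median_w(|x|) + c * MAD_w(|x|)`.  Each candidate is scored with
#' anomaly features: robust z-scores of its inter-peak interval and amplitude,
#' robust z-scores of the local variance and skewness, the excess kurtosis of
#' a +/-100 ms window, and the fraction of that window's spectral power
#' outside the modality's physiological band (ECG 0.5-40 Hz, PCG 25-400 Hz).
#' A peak with at least `votes` features past their cutoffs is flagged false
#' and its +/-100 ms neighbourhood is replaced by cubic interpolation from the
#' flanking samples.  Samples more than 100 ms from any flagged peak are never
#' altered.
#'
#' @param x numeric signal (at least 2 s).
#' @param fs sampling rate in Hz.
#' @param modality `"ECG"` or `"PCG"`.
#' @param cfg an [fpe_config()].
#' @return list with `cleaned` (numeric vector) and `peaks`, a data frame with
#'   columns `index`, `amplitude`, the feature columns and `is_false`.
#' @export
false_peak_elimination <- function(x, fs, modality = c("ECG", "PCG"),
                                   cfg = fpe_config()) {
  modality <- match.arg(modality)
  if (fs <= 0) stop("fs must be > 0")
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")
  empty <- data.frame(index = integer(), amplitude = numeric(),
                      interval_z = numeric(), amplitude_z = numeric(),
                      local_variance = numeric(), local_skewness = numeric(),
                      local_kurtosis = numeric(), band_power_ratio = numeric(),
                      is_false = logical())
  ax <- abs(x)
  if (max(ax) == 0) {
    warning("all-zero signal: no peaks to assess")
    return(list(cleaned = x, peaks = empty))
  }
  theta <- adaptive_threshold(ax, fs, cfg$window_s, cfg$c)
  n <- length(x)
  core <- 2:(n - 1L)
  cand <- core[ax[core] > ax[core - 1L] & ax[core] >= ax[core + 1L] &
                 ax[core] >= theta[core]]
  # refractory merge: keep the larger of any two candidates closer than 200 ms
  if (length(cand) > 1L) {
    gap <- as.integer(round(cfg$refractory_s * fs))
    keep <- logical(length(cand))
    ord <- order(ax[cand], decreasing = TRUE)
    taken <- integer()
    for (i in ord) {
      if (!length(taken) || all(abs(cand[i] - taken) >= gap)) {
        keep[i] <- TRUE
        taken <- c(taken, cand[i])
      }
    }
    cand <- cand[keep]
  }
  if (length(cand) < 2L) {
    warning("fewer than 2 candidate peaks: intervals undefined, ",
            "returning input unchanged")
    return(list(cleaned = x, peaks = empty))
  }
  cand <- sort(cand)
  amp <- ax[cand]
  iv <- diff(cand) / fs
  per_iv <- c(iv[1L], iv)            # each peak owns the interval to its left
  half <- as.integer(round(cfg$local_s * fs))
  feats <- t(vapply(cand, function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    c(var = stats::var(w),
      skew = e1071::skewness(w, type = 2),
      kurt = e1071::kurtosis(w, type = 2),
      ratio = out_of_band_ratio(w, fs, physio_band(modality)))
  }, numeric(4)))
  feats[!is.finite(feats)] <- 0
  interval_z <- robust_z(per_iv)
  amplitude_z <- robust_z(amp)
  votes <- (abs(interval_z) > cfg$z_cutoff) +
    (abs(amplitude_z) > cfg$z_cutoff) +
    (abs(robust_z(feats[, "var"])) > cfg$z_cutoff) +
    (abs(robust_z(feats[, "skew"])) > cfg$z_cutoff) +
    (feats[, "kurt"] > cfg$kurtosis_cutoff) +
    (feats[, "ratio"] > cfg$ratio_cutoff)
  is_false <- votes >= cfg$votes
  cleaned <- x
  flank <- max(4L, as.integer(round(0.05 * fs)))   # 50 ms anchor flanks
  for (i in cand[is_false]) {
    a <- max(1L, i - half); b <- min(n, i + half)
    left <- max(1L, a - flank):(a - 1L)
    right <- (b + 1L):min(n, b + flank)
    left <- left[left >= 1L & left < a]
    right <- right[right > b & right <= n]
    # smoothed anchors (binned means) keep the cubic from overshooting on
    # noisy flanks
    bin_anchors <- function(idx, nb = 4L) {
      if (!length(idx)) return(NULL)
      g <- cut(seq_along(idx), breaks = min(nb, length(idx)), labels = FALSE)
      data.frame(x = tapply(idx, g, mean), y = tapply(cleaned[idx], g, mean))
    }
    anc <- rbind(bin_anchors(left), bin_anchors(right))
    if (!is.null(anc) && nrow(anc) >= 2L) {
      cleaned[a:b] <- stats::spline(anc$x, anc$y, xout = a:b,
                                    method = "natural")$y
    } else {
      cleaned[a:b] <- 0
    }
  }
  peaks <- data.frame(index = cand, amplitude = x[cand],
                      interval_z = interval_z, amplitude_z = amplitude_z,
                      local_variance = feats[, "var"],
                      local_skewness = feats[, "skew"],
                      local_kurtosis = feats[, "kurt"],
                      band_power_ratio = feats[, "ratio"],
                      is_false = is_false)
  list(cleaned = cleaned, peaks = peaks)
}

# ---- segmentation ----------------------------------------------------------

#' Segmentation configuration
#'
#' Fixed window with class-dependent stride: 8-s windows, 8-s stride for
#' positive recordings and 3-s stride for negative ones, which rebalances a
#' roughly 2.4:1 subject ratio to about 1:1 at the segment level.
#'
#' @param window_s window length (s), default 8.
#' @param stride_positive_s stride for positive-class records (s), default 8.
#' @param stride_negative_s stride for negative-class records (s), default 3.
#' @return a `SegmentationConfig` list.
#' @export
segmentation_config <- function(window_s = 8, stride_positive_s = 8,
                                stride_negative_s = 3) {
  if (window_s <= 0 || stride_positive_s <= 0 || stride_negative_s <= 0)
    stop("window and strides must be > 0")
  structure(list(window_s = window_s,
                 stride_positive_s = stride_positive_s,
                 stride_negative_s = stride_negative_s),
            class = "SegmentationConfig")
}

#' Cut a record into fixed-length windows
#'
#' Window starts are `0, s, 2s, ...` samples, giving
#' `floor((L - w) / s) + 1` segments for a record of `L` samples with window
#' `w` and stride `s` (all in samples).  A record shorter than the window
#' yields an empty archive with a message.
#'
#' @param rec a `SignalRecord`.
#' @param cfg a [segmentation_config()].
#' @return a [segment_archive()] with per-segment provenance.
#' @export
segment_signal <- function(rec, cfg = segmentation_config()) {
  w <- as.integer(round(cfg$window_s * rec$fs))
  stride_s <- if (is_positive_label(rec$label)) cfg$stride_positive_s else
    cfg$stride_negative_s
  s <- as.integer(round(stride_s * rec$fs))
  L <- length(rec$samples)
  if (L < w) {
    message("record ", rec$record_id, " shorter than the window (",
            sprintf("%.2f", rec$duration_s), " s < ", cfg$window_s,
            " s): skipped")
    return(segment_archive(matrix(numeric(), 0L, w), rec$fs, cfg$window_s))
  }
  k <- (L - w) %/% s + 1L
  starts <- (seq_len(k) - 1L) * s
  segs <- t(vapply(starts, function(s0) rec$samples[(s0 + 1L):(s0 + w)],
                   numeric(w)))
  segment_archive(segs, rec$fs, cfg$window_s,
                  labels = rep(rec$label, k),
                  provenance = data.frame(record_id = rep(rec$record_id, k),
                                          start_sample = starts))
}

#' Full preprocessing chain for one record
#'
#' Wiener denoising, false-peak elimination, then segmentation; per-segment
#' min-max normalization to \[0, 1\] follows so window amplitudes are
#' comparable.
#'
#' @param rec a `SignalRecord` (already at the target rate).
#' @param wiener a [wiener_config()], or `NULL` to skip denoising.
#' @param fpe an [fpe_config()], or `NULL` to skip false-peak removal.
#' @param seg a [segmentation_config()].
#' @param normalize logical: min-max normalize each segment to \[0, 1\].
#' @return a [segment_archive()].
#' @export
preprocess_record <- function(rec, wiener = wiener_config(),
                              fpe = fpe_config(),
                              seg = segmentation_config(),
                              normalize = TRUE) {
  x <- rec$samples
  if (!is.null(wiener)) x <- as.numeric(wiener_filter(x, wiener))
  if (!is.null(fpe))
    x <- suppressWarnings(
      false_peak_elimination(x, rec$fs, rec$modality, fpe)$cleaned)
  rec2 <- signal_record(x, rec$fs, modality = rec$modality, label = rec$label,
                        record_id = rec$record_id, meta = rec$meta)
  arc <- segment_signal(rec2, seg)
  if (normalize && nrow(arc$segments) > 0L) {
    arc$segments <- t(apply(arc$segments, 1L, function(r)
      suppressWarnings(minmax_normalize(r))))
  }
  arc
}
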