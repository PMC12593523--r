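# Shared fixtures: all test data is generated in code.

cp_ns <- asNamespace("cardiopyramid")

# pure tone record
make_tone <- function(freq, fs, dur, amp = 0.5) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  amp * sin(2 * pi * freq * t)
}

# band-limited signal, periodic in its window (integer cycle counts), so
# Fourier resampling is exact on it
make_bandlimited <- function(n, fs, max_frac = 0.35, n_comp = 12, seed = 1) {
  cp_ns$with_seed(seed, {
    dur <- n / fs
    kmax <- floor(max_frac * fs * dur)
    ks <- sample(seq_len(kmax), n_comp)
    t <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    for (k in ks) x <- x + rnorm(1) * sin(2 * pi * (k / dur) * t + runif(1, 0, 2 * pi))
    x / max(abs(x))
  })
}

# small quick cohort config (short recordings keep module tests fast)
quick_synth_config <- function(n_pos = 4, n_neg = 4, seed = 1, ...) {
  synth_config(n_positive = n_pos, n_negative = n_neg, seed = seed,
               duration_dist = list(meanlog = log(12), sdlog = 0.05,
                                    min = 9, max = 14), ...)
}

# numeric finite-difference gradient of f at a sample of coordinates
fd_grad <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# area under the ROC curve of a score separating two groups
auc_stat <- function(score, is_pos) {
  r <- rank(score)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
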