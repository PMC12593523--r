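# Reading, resampling and persisting biosignal records and segment archives.

#' Construct a labeled biosignal record
#'
#' A `SignalRecord` holds one single-channel sampled signal (ECG in mV, PCG in
#' normalized arbitrary units) together with its sampling rate and label.
#'
#' @param samples numeric vector of finite sample values.
#' @param fs sampling rate in Hz (> 0).
#' @param modality `"ECG"` or `"PCG"`.
#' @param label one of `"positive"`, `"negative"`, `"AD"`, `"MVP"`, `"MPC"`,
#'   `"unlabeled"`.
#' @param record_id identifier string.
#' @param meta optional list of provenance metadata (ground-truth R peaks,
#'   artifact positions, ...).
#' @return an object of class `SignalRecord`.
#' @export
signal_record <- function(samples, fs, modality = c("ECG", "PCG"),
                          label = "unlabeled", record_id = "rec",
                          meta = list()) {
  modality <- match.arg(modality)
  label <- match.arg(label, c("positive", "negative", "AD", "MVP", "MPC",
                              "unlabeled"))
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty signal: record has no samples")
  if (!all(is.finite(samples))) stop("signal contains non-finite samples")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  structure(list(record_id = record_id, modality = modality,
                 samples = samples, fs = fs, label = label,
                 duration_s = length(samples) / fs, meta = meta),
            class = "SignalRecord")
}

#' @export
print.SignalRecord <- function(x, ...) {
  cat(sprintf("<SignalRecord %s> %s, %s, %.2f s @ %g Hz (%d samples)\n",
              x$record_id, x$modality, x$label, x$duration_s, x$fs,
              length(x$samples)))
  invisible(x)
}

is_positive_label <- function(label) label %in% c("positive", "AD", "MVP", "MPC")

# ---- WAV (PCM mono, hand-rolled RIFF: no WAV reader ships with this stack) --

read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("format error in ", path, ": missing RIFF magic at byte 0")
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("format error in ", path, ": missing WAVE tag at byte 8")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, endian = "little"),
        fs = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, 2L, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("format error in ", path, ": fmt or data chunk missing")
  if (fmt$audio_format != 1L || fmt$bits != 16L)
    stop("format error in ", path, ": only 16-bit PCM WAV is supported")
  pcm <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
                 signed = TRUE, endian = "little")
  if (fmt$channels > 1L) {
    warning("multi-channel WAV: taking channel 0")
    pcm <- pcm[seq(1L, length(pcm), by = fmt$channels)]
  }
  list(samples = pcm / 32768, fs = fmt$fs)
}

#' Write a record to a 16-bit PCM mono WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit PCM.
#'
#' @param rec a `SignalRecord`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  x <- pmin(pmax(rec$samples, -1), 1 - 1 / 32768)
  pcm <- as.integer(round(x * 32768))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")      # PCM, mono
  writeBin(as.integer(rec$fs), con, size = 4L, endian = "little")
  writeBin(as.integer(rec$fs * 2L), con, size = 4L, endian = "little")
  writeBin(c(2L, 16L), con, size = 2L, endian = "little")     # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

# ---- CSV (time_s,value) ----------------------------------------------------

read_signal_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty signal: ", path, " has no rows")
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) < 2L)
    stop("format error in ", path, ": expected two columns time_s,value")
  t <- as.numeric(df[[1]]); v <- as.numeric(df[[2]])
  if (length(t) == 0L) stop("empty signal: ", path)
  if (anyNA(t) || anyNA(v))
    stop("format error in ", path, ": non-numeric entries (first bad line ",
         which(is.na(t) | is.na(v))[1] + has_header, ")")
  dt <- diff(t)
  if (length(dt) && any(dt <= 0))
    stop("dialect error in ", path, ": time column is not strictly increasing",
         " (line ", which(dt <= 0)[1] + 1L + has_header, ")")
  if (length(dt) == 0L) stop("empty signal: need at least 2 samples to infer fs")
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med))
    stop("dialect error in ", path, ": sample-time jitter exceeds 1% of the ",
         "median interval; cannot infer a sampling rate")
  list(samples = v, fs = 1 / med)
}

#' Write a record as a two-column CSV (`time_s,value`)
#'
#' @param rec a `SignalRecord`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(rec, path) {
  t <- (seq_along(rec$samples) - 1L) / rec$fs
  utils::write.csv(data.frame(time_s = t, value = rec$samples), path,
                   row.names = FALSE)
  invisible(path)
}

# ---- WFDB (header + binary data, formats 16 and 212, signal 0) -------------

read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("format error: WFDB header ", hea, " not found")
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  datfile <- sig[1]
  fmt <- as.integer(sub("x.*|:.*|\\+.*", "", sig[2]))
  gain_spec <- if (length(sig) >= 3) sig[3] else "200"
  gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_spec)))
  baseline <- if (grepl("\\(", gain_spec))
    as.numeric(sub(".*\\(([^)]*)\\).*", "\\1", gain_spec)) else
      if (length(sig) >= 5) as.numeric(sig[5]) else 0  # ADC zero fallback
  if (is.na(gain) || gain == 0) gain <- 200
  dat <- file.path(dirname(hea), datfile)
  if (!file.exists(dat)) stop("format error: WFDB data file ", dat, " not found")
  raw <- readBin(dat, "raw", file.size(dat))
  if (fmt == 16L) {
    adc <- readBin(raw, "integer", length(raw) %/% 2L, 2L, signed = TRUE,
                   endian = "little")
    if (nsig > 1L) {
      warning("multi-signal WFDB record: taking signal 0")
      adc <- adc[seq(1L, length(adc), by = nsig)]
    }
  } else if (fmt == 212L) {
    b <- as.integer(raw)
    ntrip <- length(b) %/% 3L
    i <- seq_len(ntrip)
    b1 <- b[3L * i - 2L]; b2 <- b[3L * i - 1L]; b3 <- b[3L * i]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8L)
    s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4L), 15L), 8L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    adc <- as.vector(rbind(s1, s2))
    if (nsig > 1L) {
      warning("multi-signal WFDB record: taking signal 0")
      adc <- adc[seq(1L, length(adc), by = nsig)]
    }
  } else {
    stop("format error: WFDB format ", fmt, " not supported (16 and 212 only)")
  }
  if (!is.na(nsamp) && nsamp > 0L) adc <- adc[seq_len(min(nsamp, length(adc)))]
  if (is.na(baseline)) baseline <- 0
  list(samples = (adc - baseline) / gain, fs = fs)
}

#' Read a biosignal record from disk
#'
#' Supported containers: PCM mono WAV, two-column CSV (`time_s,value`, header
#' optional, sampling rate inferred from the median time step), and WFDB
#' header/data pairs (formats 16 and 212; gain and baseline from the header
#' are applied to yield physical units).  Multi-channel inputs are reduced to
#' channel 0 with a warning.
#'
#' @param path input file (for WFDB: the header path or the record stem).
#' @param format `"wav"`, `"csv"` or `"wfdb"`; inferred from the extension
#'   when missing.
#' @param modality `"ECG"` or `"PCG"`.
#' @param label class label, default `"unlabeled"`.
#' @param record_id identifier; defaults to the file stem.
#' @return a [signal_record()].
#' @export
read_record <- function(path, format = NULL, modality = c("ECG", "PCG"),
                        label = "unlabeled", record_id = NULL) {
  modality <- match.arg(modality)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, wav = "wav", csv = "csv", hea = "wfdb", dat = "wfdb",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  format <- match.arg(format, c("wav", "csv", "wfdb"))
  if (format != "wfdb" && !file.exists(path)) stop("file not found: ", path)
  raw <- switch(format,
                wav = read_wav(path),
                csv = read_signal_csv(path),
                wfdb = read_wfdb(path))
  if (is.null(record_id))
    record_id <- tools::file_path_sans_ext(basename(path))
  signal_record(raw$samples, raw$fs, modality = modality, label = label,
                record_id = record_id)
}

# ---- resampling ------------------------------------------------------------

fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  nk <- min(n, n_out)
  half <- nk %/% 2L
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  if (half >= 1L)
    Y[(n_out - half + 1L):n_out] <- X[(n - half + 1L):n]
  if (nk %% 2L == 0L) {
    # split the shared Nyquist bin symmetrically
    if (n_out < n) {
      Y[half + 1L] <- X[half + 1L] + X[n - half + 1L]
    } else {
      Y[half + 1L] <- X[half + 1L] / 2
      Y[n_out - half + 1L] <- X[half + 1L] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a record to a target rate
#'
#' Fourier-domain resampling (spectral truncation or zero padding): exact for
#' band-limited content below `min(fs, target_fs)/2`, and the exact identity
#' when `target_fs == fs`.  The pipeline standardizes all recordings to
#' 2000 Hz before segmentation.
#'
#' @param rec a `SignalRecord`.
#' @param target_fs target rate in Hz, default 2000.
#' @return a resampled `SignalRecord` of length `round(n * target_fs / fs)`.
#' @export
resample_record <- function(rec, target_fs = 2000) {
  if (!is.numeric(target_fs) || target_fs <= 0)
    stop("target_fs must be > 0")
  if (target_fs == rec$fs) return(rec)
  n_out <- as.integer(round(length(rec$samples) * target_fs / rec$fs))
  y <- fft_resample(rec$samples, n_out)
  meta <- rec$meta
  if (!is.null(meta$r_peaks))
    meta$r_peaks <- pmax(1L, pmin(n_out, as.integer(
      round((meta$r_peaks - 1L) * target_fs / rec$fs) + 1L)))
  signal_record(y, target_fs, modality = rec$modality, label = rec$label,
                record_id = rec$record_id, meta = meta)
}

# ---- segment archives ------------------------------------------------------

#' Construct a segment archive
#'
#' Fixed-length windows cut from one or more records, with per-segment labels
#' and provenance (source record and 0-based start sample).
#'
#' @param segments numeric matrix, one row per segment.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds; every row must have
#'   `round(window_s * fs)` samples.
#' @param labels character vector of per-segment labels.
#' @param provenance data frame with columns `record_id`, `start_sample`.
#' @return an object of class `SegmentArchive`.
#' @export
segment_archive <- function(segments, fs, window_s, labels = character(),
                            provenance = NULL) {
  if (!is.matrix(segments)) segments <- matrix(segments, nrow = 0,
                                               ncol = round(window_s * fs))
  n <- nrow(segments)
  want <- as.integer(round(window_s * fs))
  if (n > 0L && ncol(segments) != want)
    stop("invariant error: segments have ", ncol(segments),
         " samples, expected ", want)
  if (length(labels) != n)
    stop("invariant error: ", n, " segments but ", length(labels), " labels")
  if (is.null(provenance))
    provenance <- data.frame(record_id = character(n),
                             start_sample = integer(n))
  if (nrow(provenance) != n)
    stop("invariant error: provenance rows do not match segment count")
  if (n > 0L && any(provenance$start_sample < 0L))
    stop("invariant error: negative start_sample in provenance")
  structure(list(segments = segments, fs = fs, window_s = window_s,
                 labels = as.character(labels),
                 provenance = provenance),
            class = "SegmentArchive")
}

#' @export
print.SegmentArchive <- function(x, ...) {
  cat(sprintf("<SegmentArchive> %d segments of %.0f s @ %g Hz\n",
              nrow(x$segments), x$window_s, x$fs))
  if (nrow(x$segments)) print(table(x$labels))
  invisible(x)
}

#' Write / read a segment archive (HDF5)
#'
#' Single-file HDF5 container with datasets `segments` (n x L), `labels` (n),
#' `provenance_record` and `provenance_start` (n), and root attributes `fs`
#' and `window_s`.  Samples are stored as float64 so that
#' `read_archive(write_archive(x))` is bit-exact.
#'
#' @param arc a [segment_archive()].
#' @param path file path (`.h5`).
#' @return `path` invisibly (write); a `SegmentArchive` (read).
#' @export
write_archive <- function(arc, path) {
  stopifnot(inherits(arc, "SegmentArchive"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(arc$segments, path, "segments")
  rhdf5::h5write(arc$labels, path, "labels")
  rhdf5::h5write(as.character(arc$provenance$record_id), path,
                 "provenance_record")
  rhdf5::h5write(as.integer(arc$provenance$start_sample), path,
                 "provenance_start")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.numeric(arc$fs), fid, "fs")
  rhdf5::h5writeAttribute(as.numeric(arc$window_s), fid, "window_s")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (is.null(attrs$fs) || is.null(attrs$window_s))
    stop("corrupt archive: missing fs/window_s attributes in ", path)
  segs <- rhdf5::h5read(path, "segments")
  labels <- as.character(rhdf5::h5read(path, "labels"))
  prov <- data.frame(
    record_id = as.character(rhdf5::h5read(path, "provenance_record")),
    start_sample = as.integer(rhdf5::h5read(path, "provenance_start")))
  if (length(dim(segs)) != 2L) segs <- matrix(segs, nrow = length(labels))
  segment_archive(segs, fs = as.numeric(attrs$fs),
                  window_s = as.numeric(attrs$window_s),
                  labels = labels, provenance = prov)
}
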