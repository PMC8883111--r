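#' Construct a waveform
#'
#' A waveform is a sampled audio signal: a numeric vector of amplitudes in
#' arbitrary units together with its sampling rate. All stimulus generators in
#' the package return waveforms.
#'
#' @param samples Numeric vector of finite sample amplitudes.
#' @param fs Sampling rate in Hz (single positive number).
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.01, by = 1 / 44100)), fs = 44100)
#' wave_duration(w)
#' @export
waveform <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz.", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("All waveform samples must be finite.", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.numeric(fs)), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform: %d samples @ %g Hz (%.4g s), rms %.4g>\n",
    length(x$samples), x$fs, wave_duration(x), wave_rms(x)
  ))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$fs

#' Root-mean-square amplitude of a waveform
#' @param w A [waveform()].
#' @return RMS amplitude (arbitrary units).
#' @export
wave_rms <- function(w) sqrt(mean(w$samples^2))

#' Crest factor (peak / RMS) of a waveform
#'
#' Used to compare phase conventions of harmonic complexes: Schroeder phases
#' spread partial peaks in time and therefore lower the crest factor relative
#' to sine/cosine (zero) phase.
#'
#' @param w A [waveform()].
#' @return Peak absolute amplitude divided by RMS.
#' @export
crest_factor <- function(w) max(abs(w$samples)) / wave_rms(w)

#' @method tidy waveform
#' @export
tidy.waveform <- function(x, ...) {
  tibble::tibble(
    time = (seq_along(x$samples) - 1L) / x$fs,
    amplitude = x$samples
  )
}

#' @rdname autoplot-pitchonset
#' @method autoplot waveform
#' @export
autoplot.waveform <- function(object, ...) {
  df <- tidy.waveform(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)")
}

#' Apply raised-cosine on/off ramps
#'
#' Windows the first and last `ramp_duration` seconds with half raised-cosine
#' ramps. The first and last samples of the output are exactly zero.
#'
#' @param w A [waveform()].
#' @param ramp_duration Ramp length in seconds (0.020 canonical).
#' @return Ramped [waveform()].
#' @export
apply_ramps <- function(w, ramp_duration = 0.020) {
  n <- length(w$samples)
  nr <- round(ramp_duration * w$fs)
  if (2L * nr > n) stop("Ramps longer than the waveform.", call. = FALSE)
  if (nr >= 1L) {
    # half raised cosine from exactly 0 at the first sample to 1
    up <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1L) / nr))
    env <- rep(1, n)
    env[seq_len(nr)] <- up
    env[n - seq_len(nr) + 1L] <- up
    env[c(1L, n)] <- 0
    w$samples <- w$samples * env
  }
  w
}

#' Write a waveform to a RIFF/WAVE file (16-bit PCM)
#'
#' Minimal canonical-WAV writer (mono, 16-bit little-endian PCM). Samples are
#' clipped to \[-1, 1\] before quantization.
#'
#' @param w A [waveform()] with samples in \[-1, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  x <- pmin(pmax(w$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(w$fs), con, size = 4, endian = "little")
  writeBin(as.integer(w$fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono RIFF/WAVE file
#'
#' Companion to [write_wav()]; supports only the canonical layout that
#' [write_wav()] produces.
#'
#' @param path WAV file path.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("Not a RIFF file.", call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  readChar(con, 8)                                        # "WAVEfmt "
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  readBin(con, "integer", 2, size = 2, endian = "little") # fmt, channels
  fs <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
  readBin(con, "integer", 2, size = 2, endian = "little") # align, bits
  readChar(con, 4)                                        # "data"
  nb <- readBin(con, "integer", 1, size = 4, endian = "little")
  pcm <- readBin(con, "integer", nb / 2, size = 2, endian = "little")
  waveform(pcm / 32767, fs)
}
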