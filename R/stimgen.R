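#' Stimulus specification for one regular/noise sequence trial
#'
#' Parameterizes one 2300-ms trial: a regular stimulus class (harmonic
#' complex, click train, or regular-interval noise) at a fundamental frequency
#' F0, arranged as noise-regular-noise (NRN) or regular-noise-regular (RNR)
#' contiguous segments, bandpass filtered into 1-4 kHz (so all regular
#' segments are missing-fundamental stimuli), masked around F0 to cover
#' distortion products, pink-shaped, and ramped.
#'
#' @param stimulus_type One of `"HC"` (harmonic complex), `"CT"` (click
#'   train), `"RIN"` (regular-interval noise).
#' @param f0 Fundamental frequency / repetition rate in Hz (20 and 250
#'   canonical; 250 Hz is above the ~30 Hz lower limit of pitch, 20 Hz below).
#' @param sequence_order `"NRN"` or `"RNR"`.
#' @param fs Sampling rate in Hz (44100 canonical).
#' @param segment_durations Three segment durations in seconds
#'   (c(0.5, 0.9, 0.9) canonical, 2300 ms total).
#' @param passband Bandpass edges in Hz (c(1000, 4000) canonical).
#' @param masker_band_factor Masker band as multiples of `f0`
#'   (c(0.5, 1.5) canonical).
#' @param masker_gain Linear gain applied to the unit-variance masker noise
#'   (0.1 by default, i.e. -20 dB re the pre-filter signal power: enough to
#'   cover distortion products around F0 without drowning the temporal
#'   regularity of the passband signal; the absolute masker level is a free
#'   parameter of the design).
#' @param ramp_duration Raised-cosine ramp length in seconds (0.020).
#' @param rin_iterations Number of delay-and-add iterations for RIN (16).
#' @param rin_gain Delay-and-add gain (1).
#' @param rin_variant `"cascade"` or `"add_original"`, see [make_rin()].
#' @param schroeder_sign +1 or -1, sign of the Schroeder phase curvature.
#' @param seed Integer seed controlling every stochastic component of the
#'   trial (noise segments, RIN base noise, masker).
#' @return A list of class `stimulus_spec`.
#' @seealso [assemble_sequence()], [build_manifest()]
#' @export
stimulus_spec <- function(stimulus_type = c("HC", "CT", "RIN"),
                          f0 = 250,
                          sequence_order = c("NRN", "RNR"),
                          fs = 44100,
                          segment_durations = c(0.5, 0.9, 0.9),
                          passband = c(1000, 4000),
                          masker_band_factor = c(0.5, 1.5),
                          masker_gain = 0.1,
                          ramp_duration = 0.020,
                          rin_iterations = 16,
                          rin_gain = 1,
                          rin_variant = c("cascade", "add_original"),
                          schroeder_sign = 1,
                          seed = 1L) {
  stimulus_type <- match.arg(stimulus_type)
  sequence_order <- match.arg(sequence_order)
  rin_variant <- match.arg(rin_variant)
  if (f0 <= 0) stop("`f0` must be positive.", call. = FALSE)
  if (fs <= 2 * passband[2]) {
    stop("`fs` must exceed twice the upper passband edge.", call. = FALSE)
  }
  if (any(segment_durations <= 0) || length(segment_durations) != 3L) {
    stop("`segment_durations` must be three positive durations.", call. = FALSE)
  }
  if (rin_iterations < 0) stop("`rin_iterations` must be >= 0.", call. = FALSE)
  structure(
    list(
      stimulus_type = stimulus_type, f0 = f0,
      sequence_order = sequence_order, fs = fs,
      segment_durations = segment_durations, passband = passband,
      masker_band_factor = masker_band_factor, masker_gain = masker_gain,
      ramp_duration = ramp_duration, rin_iterations = rin_iterations,
      rin_gain = rin_gain, rin_variant = rin_variant,
      schroeder_sign = schroeder_sign, seed = as.integer(seed)
    ),
    class = "stimulus_spec"
  )
}

check_duration_fs <- function(duration, fs) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be a positive number of seconds.", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz.", call. = FALSE)
  }
}

#' Gaussian noise segment
#'
#' Zero-mean unit-variance Gaussian noise, the "N" segments of NRN/RNR
#' sequences and the raw material for RIN and maskers.
#'
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; the same seed reproduces the same samples.
#' @return A [waveform()] of `round(duration * fs)` samples.
#' @export
make_noise <- function(duration, fs, seed) {
  check_duration_fs(duration, fs)
  n <- round(duration * fs)
  samples <- withr::with_seed(seed, stats::rnorm(n))
  waveform(samples, fs)
}

#' Schroeder-phase harmonic complex
#'
#' Sum of equal-amplitude cosine partials at every integer multiple of `f0`
#' up to the Nyquist frequency. The n-th partial carries the Schroeder phase
#' `sign * pi * n * (n - 1) / N` (N = number of partials), which spreads the
#' partial peaks over the period and lowers the crest factor relative to
#' zero phase. The output is normalized to unit RMS.
#'
#' @param f0 Fundamental frequency in Hz (must satisfy `f0 < fs / 2`).
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param phase `"schroeder"` (default) or `"zero"` (cosine phase).
#' @param schroeder_sign +1 (up-sweep convention, default) or -1.
#' @return A [waveform()].
#' @export
make_harmonic_complex <- function(f0, duration, fs,
                                  phase = c("schroeder", "zero"),
                                  schroeder_sign = 1) {
  check_duration_fs(duration, fs)
  phase <- match.arg(phase)
  if (f0 >= fs / 2) stop("`f0` must be below the Nyquist frequency.", call. = FALSE)
  n_partials <- floor((fs / 2) / f0)
  t <- (seq_len(round(duration * fs)) - 1L) / fs
  k <- seq_len(n_partials)
  theta <- switch(phase,
    schroeder = schroeder_sign * pi * k * (k - 1) / n_partials,
    zero = rep(0, n_partials)
  )
  # outer() over (time x partial) is fine at canonical sizes
  x <- cos(outer(t, k * 2 * pi * f0) + matrix(theta, length(t), n_partials, byrow = TRUE))
  w <- waveform(rowSums(x), fs)
  w$samples <- w$samples / wave_rms(w)
  w
}

#' Click train
#'
#' Unit-amplitude single-sample impulses at multiples of `1 / f0` from t = 0;
#' every other sample is zero. The click duration is one sample (1/fs s).
#'
#' @inheritParams make_harmonic_complex
#' @return A [waveform()].
#' @export
make_click_train <- function(f0, duration, fs) {
  check_duration_fs(duration, fs)
  if (1 / f0 < 2 / fs) {
    stop("`f0` too high for the sampling rate (period < 2 samples).", call. = FALSE)
  }
  n <- round(duration * fs)
  n_clicks <- ceiling(duration * f0)
  idx <- round((seq_len(n_clicks) - 1L) * fs / f0) + 1L
  idx <- idx[idx <= n]
  samples <- numeric(n)
  samples[idx] <- 1
  waveform(samples, fs)
}

#' Regular-interval noise by iterated delay-and-add
#'
#' Starts from fresh Gaussian noise and repeatedly adds a copy of the signal
#' delayed by one period `1 / f0` (quantized to `round(fs / f0)` samples, a
#' period error of at most 0.25% at 250 Hz / 44.1 kHz). Two recursion
#' variants are provided:
#' \describe{
#'   \item{cascade}{running sum: `y_k = y_(k-1) + g * delay(y_(k-1))`}
#'   \item{add_original}{the original noise re-enters each stage:
#'     `y_k = x + g * delay(y_(k-1))`}
#' }
#' Both impose the autocorrelation peak at lag `1 / f0` that carries the
#' pitch; the variant flag records the ambiguity in the procedure's naming
#' conventions. The output is rescaled to unit variance.
#'
#' @inheritParams make_harmonic_complex
#' @param iterations Number of delay-and-add iterations (16 canonical);
#'   0 returns the base noise unchanged.
#' @param gain Delay branch gain (1 canonical).
#' @param seed Integer seed for the base noise.
#' @param variant `"cascade"` (default) or `"add_original"`.
#' @return A [waveform()].
#' @export
make_rin <- function(f0, duration, fs, iterations = 16, gain = 1, seed = 1L,
                     variant = c("cascade", "add_original")) {
  check_duration_fs(duration, fs)
  variant <- match.arg(variant)
  d <- round(fs / f0)
  if (d < 1) stop("Delay `round(fs / f0)` must be at least one sample.", call. = FALSE)
  if (iterations < 0) stop("`iterations` must be >= 0.", call. = FALSE)
  x <- make_noise(duration, fs, seed)$samples
  delay_by <- function(y) c(rep(0, d), y[seq_len(length(y) - d)])
  y <- x
  for (k in seq_len(iterations)) {
    y <- switch(variant,
      cascade = y + gain * delay_by(y),
      add_original = x + gain * delay_by(y)
    )
  }
  if (iterations > 0) y <- y / stats::sd(y)
  waveform(y, fs)
}

#' Distortion-product masker noise
#'
#' Gaussian noise bandpassed to `[0.5 * f0, 1.5 * f0]` with a 2nd-order
#' Butterworth filter, masking potential distortion products around F0 of the
#' missing-fundamental regular segments (125-375 Hz for F0 = 250, 10-30 Hz
#' for F0 = 20).
#'
#' @inheritParams make_rin
#' @param band_factor Band edges as multiples of `f0` (c(0.5, 1.5) canonical).
#' @param order Butterworth design order (2 canonical).
#' @return A [waveform()].
#' @export
make_masker <- function(f0, duration, fs, seed, band_factor = c(0.5, 1.5),
                        order = 2) {
  check_duration_fs(duration, fs)
  band <- band_factor * f0
  if (band[2] >= fs / 2) {
    stop("Masker band edge must be below the Nyquist frequency.", call. = FALSE)
  }
  w <- make_noise(duration, fs, seed)
  butterworth_bandpass(w, band[1], band[2], order = order)
}

#' Zero-phase Butterworth bandpass
#'
#' Designs a Butterworth bandpass of the requested order and applies it
#' forward-backward ([signal::filtfilt()]) so segment boundaries incur no
#' group delay; the effective magnitude response is the square of the
#' designed response.
#'
#' @param w A [waveform()].
#' @param low,high Band edges in Hz, `0 < low < high < fs / 2`.
#' @param order Designed filter order (4 canonical for the 1-4 kHz stimulus
#'   band, 2 for maskers).
#' @return Filtered [waveform()] of the same length.
#' @export
butterworth_bandpass <- function(w, low, high, order = 4) {
  fs <- w$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("Band edges must satisfy 0 < low < high < fs / 2.", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w$samples <- signal::filtfilt(bf, w$samples)
  w
}

#' Impose a 1/f (pink) power spectrum
#'
#' Filters the signal with a linear-phase FIR whose magnitude approximates
#' `1 / sqrt(f)` (so power goes as 1/f), designed by frequency sampling
#' ([signal::fir2()]). Applied as a single pass with group-delay
#' compensation, so for white-noise input the log-log spectral slope over
#' 100 Hz - 10 kHz is -1 (power vs. frequency).
#'
#' @param w A [waveform()].
#' @param n_taps FIR length - 1 (even; 500 default).
#' @return Pink-shaped [waveform()] of the same length.
#' @export
pink_shape <- function(w, n_taps = 500) {
  if (length(w$samples) == 0L) stop("Empty waveform.", call. = FALSE)
  nyq <- w$fs / 2
  f <- c(seq(0, 1, length.out = 257))
  m <- 1 / sqrt(pmax(f * nyq, 1))        # clamp below 1 Hz to avoid the DC pole
  m <- m / max(m)
  h <- signal::fir2(n_taps, f, m)
  w$samples <- fir_apply_onepass(w$samples, h)
  w
}

# Linear-phase FIR applied once, zero-phase via group-delay compensation
# and reflection padding; length preserved. h must be (close to) symmetric.
fir_apply_onepass <- function(x, h) {
  as.vector(fir_apply_matrix(matrix(x, ncol = 1), h))
}

#' Assemble one full NRN / RNR trial sequence
#'
#' Synthesizes the three contiguous segments (500, 900, 900 ms canonical),
#' concatenates them in the requested order, then applies the common
#' processing chain in order: bandpass into the stimulus passband (1-4 kHz,
#' order 4), add the masker noise, pink-shape the entire sequence, and window
#' with raised-cosine on/off ramps. Regular segments within one trial share
#' the same F0 and stimulus type; every noise and RIN realization is derived
#' from `trial_seed`, so each trial is unique. The result is normalized to
#' RMS 0.05 full scale (the absolute presentation level is a free parameter).
#'
#' @param spec A [stimulus_spec()].
#' @param trial_seed Integer seed for this trial (defaults to `spec$seed`).
#' @return A [waveform()] of `sum(segment_durations) * fs` samples whose
#'   first and last samples are exactly zero.
#' @export
assemble_sequence <- function(spec, trial_seed = spec$seed) {
  stopifnot(inherits(spec, "stimulus_spec"))
  fs <- spec$fs
  durs <- spec$segment_durations
  seeds <- derive_seeds(trial_seed, 4L)
  regular <- function(duration, seed) {
    switch(spec$stimulus_type,
      HC = make_harmonic_complex(spec$f0, duration, fs,
        schroeder_sign = spec$schroeder_sign
      ),
      CT = make_click_train(spec$f0, duration, fs),
      RIN = make_rin(spec$f0, duration, fs,
        iterations = spec$rin_iterations, gain = spec$rin_gain,
        seed = seed, variant = spec$rin_variant
      )
    )
  }
  segs <- if (spec$sequence_order == "NRN") {
    list(
      make_noise(durs[1], fs, seeds[1]),
      regular(durs[2], seeds[2]),
      make_noise(durs[3], fs, seeds[3])
    )
  } else {
    list(
      regular(durs[1], seeds[1]),
      make_noise(durs[2], fs, seeds[2]),
      regular(durs[3], seeds[3])
    )
  }
  x <- waveform(unlist(lapply(segs, `[[`, "samples")), fs)
  x <- butterworth_bandpass(x, spec$passband[1], spec$passband[2], order = 4)
  masker <- make_masker(spec$f0, wave_duration(x), fs, seeds[4],
    band_factor = spec$masker_band_factor
  )
  x$samples <- x$samples + spec$masker_gain * masker$samples
  x <- pink_shape(x)
  x <- apply_ramps(x, spec$ramp_duration)
  x$samples <- x$samples * (0.05 / wave_rms(x))
  x$samples[c(1L, length(x$samples))] <- 0
  x
}

# deterministic stream of sub-seeds from one integer seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Build a factorial session manifest
#'
#' Enumerates the 12 conditions (2 F0s x 3 stimulus types x 2 sequence
#' orders) `n_reps` times each in a seeded random order, drawing i.i.d.
#' uniform inter-stimulus intervals and a unique seed per trial so every
#' trial's noise and RIN realizations are unique. The canonical session is
#' `n_reps = 60`, i.e. 720 trials with ISIs jittered in 900-1100 ms (mean
#' 1000 ms).
#'
#' @param n_reps Repetitions per condition (60 canonical).
#' @param isi_range Inter-stimulus-interval range in ms (c(900, 1100)).
#' @param seed Integer master seed.
#' @return A tibble with columns `index`, `stimulus_type`, `f0`,
#'   `sequence_order`, `isi_ms`, `trial_seed`.
#' @examples
#' build_manifest(n_reps = 1, seed = 7)
#' @export
build_manifest <- function(n_reps = 60, isi_range = c(900, 1100), seed = 1L) {
  if (n_reps < 1) stop("`n_reps` must be at least 1.", call. = FALSE)
  conditions <- tidyr::expand_grid(
    stimulus_type = c("HC", "CT", "RIN"),
    f0 = c(20, 250),
    sequence_order = c("NRN", "RNR")
  )
  n_trials <- nrow(conditions) * n_reps
  withr::with_seed(seed, {
    trials <- conditions[rep(seq_len(nrow(conditions)), n_reps), ]
    trials <- trials[sample.int(n_trials), ]
    trials$isi_ms <- stats::runif(n_trials, isi_range[1], isi_range[2])
    trials$trial_seed <- sample.int(.Machine$integer.max - 1L, n_trials)
  })
  dplyr::mutate(trials, index = dplyr::row_number(), .before = 1)
}

#' Write / read a trial manifest as CSV
#'
#' @param manifest A manifest tibble from [build_manifest()].
#' @param path CSV file path.
#' @return `path` invisibly; `read_manifest()` returns the tibble.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      index = "i", stimulus_type = "c", f0 = "d",
      sequence_order = "c", isi_ms = "d", trial_seed = "i"
    )
  )
}

#' Canonical WAV file name for a manifest row
#'
#' `{type}{f0}{order}_{index:04d}.wav`, e.g. `HC250NRN_0001.wav`.
#'
#' @param stimulus_type,f0,sequence_order,index Manifest columns.
#' @return Character vector of file names.
#' @export
stimulus_filename <- function(stimulus_type, f0, sequence_order, index) {
  sprintf("%s%d%s_%04d.wav", stimulus_type, as.integer(f0), sequence_order,
          as.integer(index))
}

#' Write / read a stimulus configuration file
#'
#' Serializes a [stimulus_spec()] as a plain key-value (YAML) text file so
#' a stimulus set can be regenerated from its configuration alone.
#'
#' @param spec A [stimulus_spec()].
#' @param path Config file path.
#' @return `path` invisibly; `read_stimulus_config()` returns the
#'   [stimulus_spec()].
#' @export
write_stimulus_config <- function(spec, path) {
  stopifnot(inherits(spec, "stimulus_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_stimulus_config
#' @export
read_stimulus_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(stimulus_spec, vals)
}
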