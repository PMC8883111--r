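#' Specify a Hamming-window FIR filter
#'
#' Filters are linear-phase FIRs designed with a Hamming window
#' ([signal::fir1()]). The filter length follows the usual
#' transition-bandwidth heuristic (about 3.3 cycles of the transition band).
#' One-pass application is made zero-phase by compensating the constant
#' group delay; two-pass applies the filter forward and backward (squaring
#' the magnitude response), the convention used for notch filtering.
#'
#' @param kind `"highpass"`, `"lowpass"` or `"notch"`.
#' @param cutoff Cutoff frequency in Hz (for `notch`, the center frequency;
#'   may be a vector of centers, e.g. `seq(50, 550, by = 50)`).
#' @param transition_bandwidth Transition bandwidth in Hz; by default
#'   `max(min(0.25 * cutoff, 10), 2)` for lowpass, capped at the cutoff for
#'   highpass (`min(max(0.25 * cutoff, 2), cutoff)`, so a 0.5-Hz highpass
#'   gets a 0.5-Hz transition band and still nulls DC), and 1 for notch.
#' @param notch_halfwidth Half-width of each notch stop band in Hz (1).
#' @param passes 1 (delay-compensated single pass, zero-phase) or 2
#'   (forward-backward).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass", "notch"),
                        cutoff,
                        transition_bandwidth = NULL,
                        notch_halfwidth = 1,
                        passes = 1) {
  kind <- match.arg(kind)
  stopifnot(all(cutoff > 0), passes %in% c(1, 2))
  if (is.null(transition_bandwidth)) {
    transition_bandwidth <- switch(kind,
      notch = 1,
      lowpass = max(min(0.25 * min(cutoff), 10), 2),
      highpass = min(max(0.25 * min(cutoff), 2), min(cutoff))
    )
  }
  structure(
    list(kind = kind, cutoff = cutoff,
         transition_bandwidth = transition_bandwidth,
         notch_halfwidth = notch_halfwidth, passes = passes),
    class = "filter_spec"
  )
}

# Hamming FIR taps for a filter_spec at sampling rate fs
design_fir <- function(spec, fs) {
  nyq <- fs / 2
  if (any(spec$cutoff >= nyq)) {
    stop("Filter cutoff must be below the Nyquist frequency.", call. = FALSE)
  }
  n <- ceiling(3.3 * fs / spec$transition_bandwidth)
  n <- n + n %% 2                            # even order -> type I, exact delay
  switch(spec$kind,
    lowpass = signal::fir1(n, spec$cutoff / nyq, type = "low"),
    highpass = signal::fir1(n, spec$cutoff / nyq, type = "high"),
    notch = {
      h <- NULL
      for (f0 in spec$cutoff) {
        band <- c(f0 - spec$notch_halfwidth, f0 + spec$notch_halfwidth) / nyq
        hk <- signal::fir1(n, band, type = "stop")
        h <- if (is.null(h)) hk else stats::convolve(h, rev(hk), type = "open")
      }
      h
    }
  )
}

# zero-phase single pass of a (symmetric) FIR over the columns of a matrix,
# reflection-padded, length preserved
fir_apply_matrix <- function(X, h) {
  n <- nrow(X)
  nh <- length(h)
  pad <- min(nh, n - 1L)
  idx_top <- rev(seq_len(pad) + 1L)
  idx_bot <- n - seq_len(pad)
  Xp <- rbind(X[idx_top, , drop = FALSE], X, X[idx_bot, , drop = FALSE])
  np <- nrow(Xp)
  L <- stats::nextn(np + nh - 1L)
  H <- stats::fft(c(h, numeric(L - nh)))
  Xf <- stats::mvfft(rbind(Xp, matrix(0, L - np, ncol(X))))
  Y <- Re(stats::mvfft(Xf * H, inverse = TRUE)) / L
  delay <- (nh - 1L) / 2
  start <- pad + 1L + round(delay)
  Y[start:(start + n - 1L), , drop = FALSE]
}

#' Apply an FIR filter to a waveform or epoch array
#'
#' Zero-phase (no group delay at the passband center), length-preserving.
#'
#' @param x A [waveform()] or [epoch_array()].
#' @param spec A [filter_spec()].
#' @return The filtered object, same class and length.
#' @export
fir_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  h <- design_fir(spec, x$fs)
  apply_once <- function(M) fir_apply_matrix(M, h)
  run <- function(M) {
    for (p in seq_len(spec$passes)) M <- apply_once(M)
    M
  }
  if (inherits(x, "waveform")) {
    x$samples <- as.vector(run(matrix(x$samples, ncol = 1)))
  } else if (inherits(x, "epoch_array")) {
    d <- dim(x$data)
    M <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])
    M <- run(M)
    x$data <- aperm(array(M, c(d[3], d[1], d[2])), c(2, 3, 1))
  } else {
    stop("`x` must be a waveform or epoch_array.", call. = FALSE)
  }
  x
}

#' Resample an epoch array
#'
#' Applies an anti-alias FIR lowpass (cutoff 0.45 of the new sampling rate)
#' when downsampling, then evaluates the signal on the new time grid by
#' linear interpolation. The event alignment `t0` is preserved and the new
#' length is `round(n * fs_new / fs)`.
#'
#' @param x An [epoch_array()].
#' @param fs_new New sampling rate in Hz, `fs_new <= fs`.
#' @return The resampled [epoch_array()].
#' @export
resample_epochs <- function(x, fs_new) {
  stopifnot(inherits(x, "epoch_array"))
  if (fs_new > x$fs) stop("`fs_new` must not exceed the current rate.", call. = FALSE)
  if (fs_new == x$fs) return(x)
  y <- fir_filter(x, filter_spec("lowpass", 0.45 * fs_new,
                                 transition_bandwidth = 0.1 * fs_new))
  d <- dim(y$data)
  n_new <- round(d[3] * fs_new / x$fs)
  t_old <- epoch_times(x)
  t_new <- x$t0 + (seq_len(n_new) - 1L) * 1000 / fs_new
  M <- matrix(aperm(y$data, c(3, 1, 2)), nrow = d[3])
  Mn <- apply(M, 2, function(col) stats::approx(t_old, col, xout = t_new,
                                                rule = 2)$y)
  y$data <- aperm(array(Mn, c(n_new, d[1], d[2])), c(2, 3, 1))
  y$fs <- fs_new
  y
}

# pure index slicing of the time axis: [t_start, t_start + length) ms
# relative to the parent epoch's event
slice_epochs <- function(x, t_start_ms, duration_ms, new_t0_ms, condition = x$condition) {
  i0 <- round((t_start_ms - x$t0) * x$fs / 1000) + 1L
  n_w <- round(duration_ms * x$fs / 1000)
  n <- dim(x$data)[3]
  if (i0 < 1L || i0 + n_w - 1L > n) {
    stop("Requested window lies outside the parent epoch.", call. = FALSE)
  }
  epoch_array(x$data[, , i0:(i0 + n_w - 1L), drop = FALSE],
    fs = x$fs, t0 = new_t0_ms, condition = condition, subject = x$subject
  )
}

#' Transition times of the NRN / RNR sequences
#'
#' With segments of 0.5, 0.9 and 0.9 s, the segment boundaries fall at 0.5 s
#' and 1.4 s after stimulus onset; which boundary is a noise-to-regular (NR)
#' vs regular-to-noise (RN) transition depends on the sequence order.
#'
#' @param sequence_order `"NRN"` or `"RNR"`.
#' @param transition `"NR"` or `"RN"`.
#' @return Transition time in ms after stimulus onset.
#' @export
transition_time_ms <- function(sequence_order = c("NRN", "RNR"),
                               transition = c("NR", "RN")) {
  sequence_order <- match.arg(sequence_order)
  transition <- match.arg(transition)
  if (sequence_order == "NRN") {
    if (transition == "NR") 500 else 1400
  } else {
    if (transition == "NR") 1400 else 500
  }
}

#' Re-epoch around a noise/regular transition
#'
#' Pure index slicing (no interpolation) of stimulus-onset-locked epochs
#' into transition-locked epochs. The default window of -200 to +900 ms
#' around the NR transition corresponds to absolute windows of 0.3-1.4 s
#' (NRN) or 1.2-2.3 s (RNR) after stimulus onset.
#'
#' @param x An [epoch_array()] locked to stimulus onset.
#' @param sequence_order `"NRN"` or `"RNR"`.
#' @param transition `"NR"` or `"RN"`.
#' @param window Window in ms relative to the transition (c(-200, 900)).
#' @return A transition-locked [epoch_array()] with `t0 = window[1]`.
#' @export
reepoch_transitions <- function(x, sequence_order, transition,
                                window = c(-200, 900)) {
  tt <- transition_time_ms(sequence_order, transition)
  slice_epochs(x, tt + window[1], diff(window), window[1])
}

#' Re-epoch around stimulus onset
#'
#' @param x An [epoch_array()] locked to stimulus onset.
#' @param window Window in ms relative to onset (c(-200, 500)).
#' @return An onset-locked [epoch_array()] with `t0 = window[1]`.
#' @export
reepoch_onsets <- function(x, window = c(-200, 500)) {
  slice_epochs(x, window[1], diff(window), window[1])
}

#' Baseline-correct epochs against the pre-stimulus interval
#'
#' Subtracts, per trial and channel, the mean over the stimulus-onset
#' baseline window. Applied to onset-locked epochs *before* transition
#' re-epoching: the baseline is stimulus-locked, never re-taken before each
#' transition, so transition-locked pre-event means are in general nonzero.
#'
#' @param x An [epoch_array()] locked to stimulus onset.
#' @param window Baseline window in ms (c(-250, 0)), half-open.
#' @return The corrected [epoch_array()].
#' @export
baseline_correct <- function(x, window = c(-250, 0)) {
  stopifnot(inherits(x, "epoch_array"))
  i0 <- round((window[1] - x$t0) * x$fs / 1000) + 1L
  n_w <- round(diff(window) * x$fs / 1000)
  if (i0 < 1L || i0 + n_w - 1L > dim(x$data)[3]) {
    stop("Baseline window lies outside the epoch.", call. = FALSE)
  }
  bl <- apply(x$data[, , i0:(i0 + n_w - 1L), drop = FALSE], c(1, 2), mean)
  x$data <- x$data - as.vector(bl)   # recycles over the time dimension
  x
}
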