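# Welch-style averaged periodogram: split into segments, Hann-window each,
# average the periodograms. Returns freq (Hz) and power density.
psd_welch <- function(x, fs, seg_len = 4096) {
  if (inherits(x, "waveform")) {
    fs <- x$fs
    x <- x$samples
  }
  n_seg <- max(1L, floor(length(x) / seg_len))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  p <- 0
  for (i in seq_len(n_seg)) {
    seg <- x[((i - 1) * seg_len + 1):(i * seg_len)] * w
    p <- p + abs(stats::fft(seg))^2
  }
  nh <- floor(seg_len / 2)
  list(freq = (seq_len(nh) - 1) * fs / seg_len, power = p[seq_len(nh)] / n_seg)
}

band_power <- function(psd, lo, hi) {
  sum(psd$power[psd$freq >= lo & psd$freq <= hi])
}

# dB of power ratio
db10 <- function(a, b) 10 * log10(a / b)

# direct generalized-eigenvalue oracle for DSS on explicit covariances
dss_oracle <- function(C_total, C_evoked) {
  ev <- eigen(solve(C_total, C_evoked))
  ord <- order(Re(ev$values), decreasing = TRUE)
  list(values = Re(ev$values)[ord],
       vectors = Re(ev$vectors)[, ord, drop = FALSE])
}

# within-subject ANOVA oracle via stats::aov with an Error() stratum
aov_oracle <- function(y_sc, design) {
  factors <- setdiff(names(design), "condition")
  df <- data.frame(
    value = as.vector(y_sc),
    subject = factor(rep(seq_len(nrow(y_sc)), ncol(y_sc)))
  )
  for (f in factors) {
    df[[f]] <- factor(rep(design[[f]], each = nrow(y_sc)))
  }
  rhs <- paste(factors, collapse = "*")
  form <- stats::as.formula(paste(
    "value ~", rhs, "+ Error(subject/(", rhs, "))"
  ))
  fit <- summary(stats::aov(form, data = df))
  out <- list()
  for (stratum in fit) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] != "Residuals") {
        out[[terms[i]]] <- tab[i, "F value"]
      }
    }
  }
  out
}

# normalized autocorrelation at one lag (demeaned)
acf_at_lag <- function(x, lag) {
  x <- x - mean(x)
  sum(x[seq_len(length(x) - lag)] * x[(lag + 1):length(x)]) / sum(x^2)
}

# windowed ACF at the stimulus period: max over integer lags adjacent to
# fs / 250 = 176.4 samples
acf_period <- function(w, t0, t1, f0 = 250) {
  seg <- w$samples[round(t0 * w$fs):round(t1 * w$fs)]
  max(vapply(
    seq(floor(w$fs / f0) - 1, ceiling(w$fs / f0) + 1),
    function(l) acf_at_lag(seg, l), 0
  ))
}

design_2x3 <- function() {
  d <- dplyr::distinct(condition_table()[, c("stimulus_type", "f0")])
  d$condition <- paste0(d$stimulus_type, d$f0)
  d[, c("condition", "stimulus_type", "f0")]
}
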