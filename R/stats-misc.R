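#' Bonferroni-Holm correction over planned contrasts
#'
#' Step-down Holm procedure controlling the family-wise error rate across
#' `m` contrasts at level `alpha`: p-values are sorted ascending, the i-th
#' smallest is compared against `alpha / (m - i + 1)`, and rejection stops
#' at the first failure. With `m = 3` the smallest p-value must beat
#' `alpha / 3` (0.0167 at alpha 0.05).
#'
#' @param p_values Numeric vector of per-contrast p-values (optionally
#'   named).
#' @param alpha Family-wise error level (0.05).
#' @return A tibble with one row per contrast: `contrast`, `p_value`,
#'   `rank`, `step_alpha` (the threshold that contrast was compared to),
#'   `adjusted_p` (Holm-adjusted), and `significant`.
#' @examples
#' holm_correct(c(frequency = 0.0462, interaction = 0.012, type = 0.30))
#' @export
holm_correct <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  stopifnot(m >= 1, all(p_values >= 0 & p_values <= 1))
  nm <- names(p_values)
  if (is.null(nm)) nm <- as.character(seq_len(m))
  ord <- order(p_values)
  rank <- match(seq_len(m), ord)
  step_alpha <- alpha / (m - rank + 1)
  pass <- p_values[ord] <= alpha / (m - seq_len(m) + 1)
  n_reject <- if (all(pass)) m else which(!pass)[1] - 1L
  significant <- rank <= n_reject
  tibble::tibble(
    contrast = nm,
    p_value = unname(p_values),
    rank = rank,
    step_alpha = step_alpha,
    adjusted_p = stats::p.adjust(unname(p_values), method = "holm"),
    significant = significant
  )
}

#' Autocorrelation peaks of an evoked response at candidate lags
#'
#' Computes the normalized autocorrelation of an evoked time course and
#' looks for local maxima within `search_band_ms` of each candidate lag
#' (e.g. 50 ms = one period of a 20-Hz regularity, whose temporal coding
#' survives in the evoked response; no such peak is expected at 4 ms for
#' 250-Hz stimuli). Prominence is the peak value minus the median
#' autocorrelation over all positive lags up to the search limit.
#'
#' @param x An `evoked_response`, a single-channel [epoch_array()] (its
#'   trial average is used), or a numeric vector with `fs` supplied.
#' @param candidate_lags_ms Candidate lags in ms.
#' @param search_band_ms Half-width of the search window around each
#'   candidate lag (10 ms).
#' @param fs Sampling rate, required when `x` is a bare numeric vector.
#' @return A tibble with columns `candidate_lag_ms`, `peak_lag_ms` (NA when
#'   no local maximum exists in the window), `peak_value`, `prominence`.
#' @export
autocorr_peaks <- function(x, candidate_lags_ms, search_band_ms = 10,
                           fs = NULL) {
  if (inherits(x, "epoch_array")) {
    fs <- x$fs
    v <- as_evoked_vector(x)
  } else if (inherits(x, "evoked_response")) {
    fs <- x$fs
    v <- as.vector(x$data[1, ])
  } else {
    if (is.null(fs)) stop("`fs` is required for a bare numeric vector.", call. = FALSE)
    v <- as.numeric(x)
  }
  n <- length(v)
  max_lag <- round((max(candidate_lags_ms) + search_band_ms) * fs / 1000)
  if (max_lag > n / 2) {
    stop("Candidate lag exceeds half the signal length.", call. = FALSE)
  }
  v <- v - mean(v)
  denom <- sum(v^2)
  if (denom == 0) stop("Zero-variance signal.", call. = FALSE)
  r <- vapply(seq_len(max_lag), function(k) {
    sum(v[seq_len(n - k)] * v[(k + 1):n]) / denom
  }, 0)
  baseline <- stats::median(r)
  purrr::map_dfr(candidate_lags_ms, function(lag_ms) {
    k0 <- round(lag_ms * fs / 1000)
    band <- round(search_band_ms * fs / 1000)
    lo <- max(2L, k0 - band)
    hi <- min(max_lag - 1L, k0 + band)
    ks <- lo:hi
    is_max <- r[ks] > r[ks - 1L] & r[ks] >= r[ks + 1L]
    if (!any(is_max)) {
      return(tibble::tibble(
        candidate_lag_ms = lag_ms, peak_lag_ms = NA_real_,
        peak_value = NA_real_, prominence = NA_real_
      ))
    }
    peaks <- ks[is_max]
    best <- peaks[which.max(r[peaks])]
    tibble::tibble(
      candidate_lag_ms = lag_ms,
      peak_lag_ms = best * 1000 / fs,
      peak_value = r[best],
      prominence = r[best] - baseline
    )
  })
}
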