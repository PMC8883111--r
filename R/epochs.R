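#' Construct an epoch array
#'
#' The package's container for segmented M/EEG-like data: a numeric array of
#' shape (trial x channel x time) with a sampling rate and the time (in ms)
#' of the first sample relative to the event the epochs are locked to.
#'
#' @param data Numeric array (trial x channel x time), all finite.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in ms relative to the event
#'   (e.g. -250 for epochs starting 250 ms before stimulus onset).
#' @param condition Optional condition label.
#' @param subject Optional subject id.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, fs, t0, condition = NA_character_, subject = NA) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a (trial x channel x time) array.", call. = FALSE)
  }
  if (anyNA(data)) stop("Epoch data must be finite.", call. = FALSE)
  structure(
    list(
      data = data, fs = as.numeric(fs), t0 = as.numeric(t0),
      condition = condition, subject = subject
    ),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_array: %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] ms%s%s>\n",
    d[1], d[2], d[3], x$fs, x$t0, max(epoch_times(x)),
    if (!is.na(x$condition)) paste0(", condition ", x$condition) else "",
    if (!is.na(x$subject)) paste0(", subject ", x$subject) else ""
  ))
  invisible(x)
}

#' Time axis of an epoch array (ms relative to the event)
#' @param x An [epoch_array()] or evoked response.
#' @return Numeric vector of sample times in ms.
#' @export
epoch_times <- function(x) {
  n_time <- if (inherits(x, "epoch_array")) dim(x$data)[3] else ncol(x$data)
  x$t0 + (seq_len(n_time) - 1L) * 1000 / x$fs
}

#' Trial-averaged evoked response
#'
#' @param x An [epoch_array()].
#' @return An object of class `evoked_response`: a (channel x time) matrix
#'   with `fs`, `t0` and labels.
#' @export
evoked <- function(x) {
  stopifnot(inherits(x, "epoch_array"))
  m <- colMeans(x$data)                      # average over the trial dim
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  structure(
    list(data = m, fs = x$fs, t0 = x$t0, condition = x$condition,
         subject = x$subject),
    class = "evoked_response"
  )
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf(
    "<evoked_response: %d channels x %d samples @ %g Hz, t0 = %g ms>\n",
    nrow(x$data), ncol(x$data), x$fs, x$t0
  ))
  invisible(x)
}

#' @method tidy epoch_array
#' @export
tidy.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_ms = rep(epoch_times(x), each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' @method tidy evoked_response
#' @export
tidy.evoked_response <- function(x, ...) {
  tibble::tibble(
    channel = rep(seq_len(nrow(x$data)), times = ncol(x$data)),
    time_ms = rep(epoch_times(x), each = nrow(x$data)),
    value = as.vector(x$data)
  )
}

#' @rdname autoplot-pitchonset
#' @method autoplot evoked_response
#' @export
autoplot.evoked_response <- function(object, ...) {
  df <- tidy.evoked_response(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_ms, y = .data$value, group = .data$channel
  )) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (a.u.)")
}

#' Write / read an epoch array as a long-format CSV
#'
#' Plain-text serialization of the epoch container: one row per
#' (trial, channel, sample), with `fs`, `t0`, `condition` and `subject`
#' carried in comment header lines. Intended for small desk-scale epochs.
#'
#' @param x An [epoch_array()].
#' @param path CSV file path.
#' @return `path` invisibly; `read_epochs_csv()` returns the [epoch_array()].
#' @export
write_epochs_csv <- function(x, path) {
  hdr <- sprintf(
    "# fs=%g t0=%g condition=%s subject=%s",
    x$fs, x$t0, x$condition, x$subject
  )
  writeLines(hdr, path)
  readr::write_csv(tidy.epoch_array(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_epochs_csv
#' @export
read_epochs_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  kv <- stats::setNames(
    sub("^[^=]+=", "", kv),
    sub("=.*$", "", kv)
  )
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  d <- c(max(df$trial), max(df$channel), length(unique(df$time_ms)))
  arr <- array(NA_real_, d)
  arr[cbind(df$trial, df$channel, match(df$time_ms, sort(unique(df$time_ms))))] <- df$value
  epoch_array(arr,
    fs = as.numeric(kv[["fs"]]), t0 = as.numeric(kv[["t0"]]),
    condition = kv[["condition"]], subject = kv[["subject"]]
  )
}
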