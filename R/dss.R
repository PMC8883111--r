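#' Trial-total and evoked channel covariances
#'
#' The two covariances that define the DSS bias: `C_total`, the average over
#' trials of the per-trial channel covariance (each trial demeaned over
#' time), and `C_evoked`, the channel covariance of the trial-averaged data.
#' Both are symmetric positive semi-definite; activity that is reproducible
#' across trials survives in `C_evoked`, while trial-varying noise averages
#' out.
#'
#' When given a list of epoch arrays (e.g. one per condition), trials are
#' pooled: `C_total` averages per-trial covariances over all trials of all
#' arrays and `C_evoked` is the covariance of the grand average over every
#' pooled trial.
#'
#' @param x An [epoch_array()] with at least 2 trials, or a list of epoch
#'   arrays sharing channels and time axes.
#' @return A list with elements `C_total` and `C_evoked`
#'   (channel x channel matrices).
#' @export
dss_covariances <- function(x) {
  if (is.list(x) && !inherits(x, "epoch_array")) {
    return(dss_covariances_multi(x))
  }
  stopifnot(inherits(x, "epoch_array"))
  d <- dim(x$data)
  if (d[1] < 2L) stop("At least 2 trials are required.", call. = FALSE)
  n_time <- d[3]
  dm <- x$data - as.vector(rowMeans(x$data, dims = 2))  # demean over time
  ap <- aperm(dm, c(2, 3, 1))                  # channel x time x trial
  C_total <- tcrossprod(matrix(ap, d[2])) / (n_time * d[1])
  avg <- rowMeans(ap, dims = 2)
  C_evoked <- tcrossprod(avg) / n_time
  list(C_total = C_total, C_evoked = C_evoked)
}

# pooled covariances over a list of epoch arrays without materializing the
# concatenated trial dimension
dss_covariances_multi <- function(xs) {
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "epoch_array")))
  n_ch <- dim(xs[[1]]$data)[2]
  n_time <- dim(xs[[1]]$data)[3]
  C_total <- matrix(0, n_ch, n_ch)
  grand <- matrix(0, n_ch, n_time)
  n_trials <- 0L
  for (x in xs) {
    d <- dim(x$data)
    stopifnot(d[2] == n_ch, d[3] == n_time)
    dm <- x$data - as.vector(rowMeans(x$data, dims = 2))
    ap <- aperm(dm, c(2, 3, 1))
    C_total <- C_total + tcrossprod(matrix(ap, n_ch)) / n_time
    grand <- grand + rowMeans(ap, dims = 2) * d[1]
    n_trials <- n_trials + d[1]
  }
  if (n_trials < 2L) stop("At least 2 trials are required.", call. = FALSE)
  list(
    C_total = C_total / n_trials,
    C_evoked = tcrossprod(grand / n_trials) / n_time
  )
}

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit a denoising source separation (DSS) model
#'
#' Finds spatial filters (linear channel combinations) that maximize the
#' "bias" function: the ratio of evoked (trial-averaged) power to total
#' power. Solved as the generalized eigenproblem
#' `C_evoked w = lambda C_total w` via whitening: eigendecompose `C_total`,
#' truncate eigenvalues below `rank_tolerance` times the largest, whiten,
#' and eigendecompose the whitened `C_evoked`. The generalized eigenvalues
#' are the per-component bias scores (evoked-to-total power ratios in
#' \[0, 1\], descending); the first component (DSS1) attains the maximal
#' ratio over all linear channel combinations.
#'
#' @param x An [epoch_array()] with >= 2 trials and >= 2 channels, or a
#'   list of epoch arrays whose trials are pooled (see
#'   [dss_covariances()]).
#' @param rank_tolerance Relative eigenvalue cutoff for the whitening
#'   truncation (1e-9).
#' @return An object of class `dss_model` with `filters`
#'   (component x channel), `patterns` (channel x component, the
#'   pseudo-inverse field maps), `bias_scores` (descending), and
#'   `rank_used`.
#' @export
dss_fit <- function(x, rank_tolerance = 1e-9) {
  first <- if (inherits(x, "epoch_array")) x else x[[1]]
  d <- dim(first$data)
  if (d[2] < 2L) {
    stop("DSS requires at least 2 channels.", call. = FALSE)
  }
  cv <- dss_covariances(x)
  et <- eigen(cv$C_total, symmetric = TRUE)
  keep <- et$values > rank_tolerance * max(et$values)
  if (!any(keep)) stop("C_total is fully rank-deficient.", call. = FALSE)
  W <- et$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(et$values[keep]),
                                                 sum(keep))
  Cw <- crossprod(W, cv$C_evoked %*% W)
  Cw <- (Cw + t(Cw)) / 2
  ew <- eigen(Cw, symmetric = TRUE)
  filters <- t(W %*% ew$vectors)              # component x channel
  structure(
    list(
      filters = filters,
      patterns = pinv(filters),
      bias_scores = pmin(pmax(ew$values, 0), 1),
      rank_used = sum(keep)
    ),
    class = "dss_model"
  )
}

#' @export
print.dss_model <- function(x, ...) {
  cat(sprintf(
    "<dss_model: %d components over %d channels (rank %d), DSS1 bias %.3f>\n",
    nrow(x$filters), ncol(x$filters), x$rank_used, x$bias_scores[1]
  ))
  invisible(x)
}

#' @method tidy dss_model
#' @export
tidy.dss_model <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$bias_scores),
    bias_score = x$bias_scores
  )
}

#' @method glance dss_model
#' @export
glance.dss_model <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$filters),
    rank_used = x$rank_used,
    dss1_bias = x$bias_scores[1]
  )
}

#' Project trials onto one DSS component
#'
#' DSS acts as a spatial filter on unaveraged trials: every trial is
#' projected onto the k-th filter, preserving the trial dimension.
#'
#' @param x The [epoch_array()] the model was fit on (or compatible data).
#' @param model A [dss_fit()] result.
#' @param k Component index (1 = DSS1).
#' @return An [epoch_array()] with one virtual channel.
#' @export
dss_timeseries <- function(x, model, k = 1) {
  stopifnot(inherits(model, "dss_model"))
  if (k < 1 || k > nrow(model$filters)) {
    stop("Component index out of range.", call. = FALSE)
  }
  d <- dim(x$data)
  w <- model$filters[k, ]
  p <- w %*% matrix(aperm(x$data, c(2, 1, 3)), d[2])   # 1 x (trial*time)
  out <- array(p, c(1L, d[1], d[3]))
  out <- aperm(out, c(2, 1, 3))
  epoch_array(out, fs = x$fs, t0 = x$t0, condition = x$condition,
              subject = x$subject)
}

#' Evoked-to-total power ratio of a single-channel epoch array
#'
#' Power of the trial average divided by the average per-trial power (each
#' trial demeaned over time, matching the covariance convention of
#' [dss_covariances()]). Equals 1 for perfectly reproducible trials and
#' about `1 / n_trials` for independent zero-mean noise.
#'
#' @param x An [epoch_array()] with one channel and >= 2 trials.
#' @return A fraction in \[0, 1\].
#' @export
evoked_power_ratio <- function(x) {
  d <- dim(x$data)
  if (d[1] < 2L) stop("At least 2 trials are required.", call. = FALSE)
  if (d[2] != 1L) stop("`x` must have a single (virtual) channel.", call. = FALSE)
  M <- matrix(x$data[, 1, ], d[1], d[3])
  M <- M - rowMeans(M)
  total <- mean(M^2)
  if (total == 0) stop("Zero total power.", call. = FALSE)
  mean(colMeans(M)^2) / total
}

#' Align component polarities to a reference
#'
#' DSS component signs are arbitrary (filter and pattern signs cancel).
#' Each component's evoked response is correlated with the reference evoked
#' response and multiplied by the sign of that correlation; an exactly zero
#' correlation leaves the sign at +1.
#'
#' @param components A list of single-channel [epoch_array()] (or
#'   `evoked_response`) objects sharing the reference's time axis.
#' @param reference A single-channel [epoch_array()] or `evoked_response`
#'   to align to (e.g. DSS1 of a representative subject and condition).
#' @return The list with signs flipped where needed.
#' @export
align_polarity <- function(components, reference) {
  ref <- as_evoked_vector(reference)
  lapply(components, function(cmp) {
    v <- as_evoked_vector(cmp)
    if (length(v) != length(ref)) {
      stop("Components and reference must share the time axis.", call. = FALSE)
    }
    r <- sum((v - mean(v)) * (ref - mean(ref)))
    s <- if (r < 0) -1 else 1
    if (inherits(cmp, "epoch_array")) cmp$data <- cmp$data * s
    else cmp$data <- cmp$data * s
    cmp
  })
}

as_evoked_vector <- function(x) {
  if (inherits(x, "epoch_array")) as.vector(evoked(x)$data[1, ])
  else if (inherits(x, "evoked_response")) as.vector(x$data[1, ])
  else as.numeric(x)
}
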