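#' Transition-locked evoked inference pipeline on synthetic cohorts
#'
#' Runs the full evoked-response inference chain on a simulated cohort:
#' for each subject, simulate stimulus-onset-locked epochs for all 12
#' conditions, baseline-correct against the pre-stimulus interval, fit DSS
#' on the trials pooled across conditions (or per condition), project every
#' trial onto DSS1, align the component polarity to a reference subject,
#' re-epoch around the requested noise/regular transition, and average
#' trials into one evoked time course per (subject, stimulus type, F0)
#' cell (NRN and RNR trials contribute their respective transition
#' windows). The resulting subject x 6-cell x time array is tested with a
#' sample-wise two-way RM-ANOVA (Stimulus Type x Frequency) and
#' cluster-based permutation inference for the requested effect.
#'
#' Subjects are processed one at a time so memory stays flat in cohort
#' size.
#'
#' @param cfg A [synth_config()].
#' @param transition `"NR"` (default) or `"RN"`.
#' @param effect Effect to test: `"f0"` (default), `"stimulus_type"`, or
#'   `"f0:stimulus_type"`.
#' @param window Re-epoching window in ms around the transition
#'   (c(-200, 900)).
#' @param threshold_p Cluster-forming threshold (0.001).
#' @param n_perm Number of permutations (1000 default at desk scale;
#'   10000 canonical).
#' @param dss_mode `"pooled"` (one DSS fit per subject across all
#'   conditions, default) or `"per_condition"`.
#' @param seed Integer seed for the permutation test (the cohort itself is
#'   controlled by `cfg$seed`).
#' @return A list of class `pipeline_result`: `evoked` (tibble of
#'   subject x cell evoked time courses), `anova` (tidy F map),
#'   `clusters` (a `cluster_result`), `times_ms`, `design`, and
#'   `dss1_bias` (per-subject DSS1 evoked-to-total ratios).
#' @export
run_transition_pipeline <- function(cfg,
                                    transition = "NR",
                                    effect = "f0",
                                    window = c(-200, 900),
                                    threshold_p = 0.001,
                                    n_perm = 1000,
                                    dss_mode = c("pooled", "per_condition"),
                                    seed = 1L) {
  dss_mode <- match.arg(dss_mode)
  reference <- NULL
  rows <- vector("list", cfg$n_subjects)
  bias <- numeric(cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    sub <- simulate_subject(cfg, s)
    sub$epochs <- lapply(sub$epochs, baseline_correct)
    if (dss_mode == "pooled") {
      model <- dss_fit(sub$epochs)
      bias[s] <- model$bias_scores[1]
      dss1 <- lapply(sub$epochs, dss_timeseries, model = model, k = 1)
      # one polarity flip per subject, taken on the pooled evoked response
      pooled_ev <- Reduce(`+`, lapply(dss1, function(e) evoked(e)$data)) /
        length(dss1)
      pooled_ev <- structure(
        list(data = pooled_ev, fs = cfg$fs, t0 = cfg$epoch_window[1],
             condition = "pooled", subject = s),
        class = "evoked_response"
      )
      if (is.null(reference)) reference <- pooled_ev
      sgn <- polarity_sign(pooled_ev, reference)
      dss1 <- lapply(dss1, function(e) { e$data <- e$data * sgn; e })
    } else {
      models <- lapply(sub$epochs, dss_fit)
      bias[s] <- mean(vapply(models, function(m) m$bias_scores[1], 0))
      dss1 <- purrr::map2(sub$epochs, models, dss_timeseries, k = 1)
      if (is.null(reference)) reference <- evoked(dss1[[1]])
      dss1 <- align_polarity(dss1, reference)
    }
    trans <- purrr::map2(dss1, sub$sequence_order, function(e, ord) {
      reepoch_transitions(e, ord, transition, window)
    })
    rows[[s]] <- dplyr::mutate(
      dplyr::select(sub, "subject", "stimulus_type", "f0", "sequence_order"),
      evoked = lapply(trans, function(e) as.vector(evoked(e)$data[1, ]))
    )
  }
  evoked_tbl <- dplyr::bind_rows(rows) |>
    # NRN and RNR trials both contribute transition epochs to the same cell
    dplyr::group_by(.data$subject, .data$stimulus_type, .data$f0) |>
    dplyr::summarise(
      evoked = list(Reduce(`+`, .data$evoked) / dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(cell = paste0(.data$stimulus_type, .data$f0))

  design <- dplyr::distinct(
    evoked_tbl, condition = .data$cell, .data$stimulus_type, .data$f0
  )
  n_time <- length(evoked_tbl$evoked[[1]])
  subjects <- sort(unique(evoked_tbl$subject))
  arr <- array(NA_real_, c(length(subjects), nrow(design), n_time),
               dimnames = list(NULL, design$condition, NULL))
  for (r in seq_len(nrow(evoked_tbl))) {
    arr[
      match(evoked_tbl$subject[r], subjects),
      match(evoked_tbl$cell[r], design$condition),
    ] <- evoked_tbl$evoked[[r]]
  }
  fs <- cfg$fs
  times_ms <- window[1] + (seq_len(n_time) - 1L) * 1000 / fs
  anova_tbl <- rm_anova(arr, design)
  clusters <- cluster_permutation_test(
    arr, design, effect,
    threshold_p = threshold_p, n_perm = n_perm, seed = seed
  )
  structure(
    list(
      evoked = evoked_tbl, anova = anova_tbl, clusters = clusters,
      times_ms = times_ms, design = design, dss1_bias = bias,
      transition = transition, effect = effect
    ),
    class = "pipeline_result"
  )
}

# concatenate the trial dimension of epoch arrays sharing time axes
pool_epochs <- function(epoch_list) {
  d <- dim(epoch_list[[1]]$data)
  stopifnot(all(vapply(epoch_list, function(e) identical(dim(e$data)[2:3], d[2:3]), TRUE)))
  data <- do.call(abind3, lapply(epoch_list, `[[`, "data"))
  e1 <- epoch_list[[1]]
  epoch_array(data, fs = e1$fs, t0 = e1$t0, condition = "pooled",
              subject = e1$subject)
}

# rbind 3-D arrays along the first (trial) dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n1 <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, c(n1, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

polarity_sign <- function(ev, reference) {
  v <- as.vector(ev$data[1, ])
  r <- as.vector(reference$data[1, ])
  s <- sum((v - mean(v)) * (r - mean(r)))
  if (s < 0) -1 else 1
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result: %s transition, effect %s, %d subjects>\n",
    x$transition, x$effect, length(x$dss1_bias)
  ))
  cat(sprintf("  mean DSS1 evoked/total ratio: %.3f\n", mean(x$dss1_bias)))
  print(x$clusters)
  invisible(x)
}

#' Does a significant cluster contain a given time?
#'
#' @param result A `pipeline_result` or `cluster_result` (the latter needs
#'   `times_ms`).
#' @param time_ms Time of interest in ms (e.g. 140, the pitch-onset
#'   latency).
#' @param alpha Cluster-wise level (0.05).
#' @param times_ms Time axis when `result` is a bare `cluster_result`.
#' @return TRUE if any cluster with `p_value <= alpha` contains `time_ms`.
#' @export
cluster_contains_time <- function(result, time_ms, alpha = 0.05,
                                  times_ms = NULL) {
  if (inherits(result, "pipeline_result")) {
    times_ms <- result$times_ms
    result <- result$clusters
  }
  stopifnot(inherits(result, "cluster_result"), !is.null(times_ms))
  sig <- dplyr::filter(result$clusters, .data$p_value <= alpha)
  if (nrow(sig) == 0L) return(FALSE)
  any(vapply(sig$members, function(m) {
    min(times_ms[m]) <= time_ms && max(times_ms[m]) >= time_ms
  }, TRUE))
}
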