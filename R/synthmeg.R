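#' The 12-condition factorial design table
#'
#' Two fundamental frequencies (20, 250 Hz) x three stimulus types
#' (HC, CT, RIN) x two sequence orders (NRN, RNR).
#'
#' @return A tibble with columns `condition`, `stimulus_type`, `f0`,
#'   `sequence_order`.
#' @export
condition_table <- function() {
  tidyr::expand_grid(
    stimulus_type = c("HC", "CT", "RIN"),
    f0 = c(20, 250),
    sequence_order = c("NRN", "RNR")
  ) |>
    dplyr::mutate(
      condition = paste0(.data$stimulus_type, .data$f0, .data$sequence_order),
      .before = 1
    )
}

#' Default planted-component table for the synthetic MEG generator
#'
#' One row per latent evoked component and (stimulus type, F0) cell, giving
#' its per-condition amplitude and its Gabor parameters (latency relative to
#' its anchor event, Gaussian width, carrier frequency). The defaults encode
#' the qualitative response structure the generator emulates:
#' \itemize{
#'   \item an energy-onset response at ~100 ms for every condition;
#'   \item an early regularity-onset response at ~90 ms for 20-Hz HC and CT
#'     (absent for RIN20, whose transitions evoke no response);
#'   \item a pitch-onset response at ~140 ms for all 250-Hz conditions, with
#'     RIN250 at 0.7x the HC/CT amplitude;
#'   \item a sustained regularity response over the regular segment;
#'   \item a 20-Hz steady-state component over the regular segment for
#'     20-Hz HC and CT (stronger for CT), the temporal coding of
#'     pitch-irrelevant regularity that shows up as an autocorrelation peak
#'     at the 50-ms lag of the evoked response; absent for RIN20 and all
#'     250-Hz conditions;
#'   \item a small sound-offset response.
#' }
#' Amplitudes are qualitative stand-ins in arbitrary units; no quantitative
#' per-condition amplitudes are assumed.
#'
#' @return A tibble with columns `component`, `anchor` (one of `onset`,
#'   `nr_transition`, `offset`), `latency_ms`, `width_ms`, `freq_hz`,
#'   `stimulus_type`, `f0`, `amplitude`.
#' @export
default_component_table <- function() {
  cells <- tidyr::expand_grid(
    stimulus_type = c("HC", "CT", "RIN"), f0 = c(20, 250)
  )
  comp <- function(component, anchor, latency_ms, width_ms, freq_hz, amp_fun) {
    dplyr::mutate(cells,
      component = component, anchor = anchor, latency_ms = latency_ms,
      width_ms = width_ms, freq_hz = freq_hz,
      amplitude = purrr::map2_dbl(.data$stimulus_type, .data$f0, amp_fun),
      .before = 1
    )
  }
  dplyr::bind_rows(
    comp("energy_onset", "onset", 100, 30, 9, function(st, f0) 1.0),
    comp("regularity_onset_early", "nr_transition", 90, 25, 11,
         function(st, f0) if (f0 == 20 && st != "RIN") 0.6 else 0),
    comp("pitch_onset", "nr_transition", 140, 30, 9,
         function(st, f0) {
           if (f0 != 250) 0 else if (st == "RIN") 0.7 * 0.8 else 0.8
         }),
    comp("sustained", "nr_transition", 450, 250, 0,
         function(st, f0) if (st == "RIN" && f0 == 20) 0 else 0.25),
    comp("steady_state", "nr_transition", 450, 220, 20,
         function(st, f0) {
           if (f0 != 20) 0 else switch(st, CT = 0.4, HC = 0.3, RIN = 0)
         }),
    comp("offset", "offset", 100, 30, 9, function(st, f0) 0.2)
  )
}

#' Configuration for the synthetic multi-subject MEG generator
#'
#' Defines the cohort and noise model for [simulate_cohort()] /
#' [simulate_subject()]. The canonical cohort size (19 subjects) and
#' sampling rate (600 Hz, the post-downsampling rate of the evoked-response
#' pipeline) are the canonical recording conditions; channel and
#' trial counts default to desk-scale values.
#'
#' @param n_subjects Cohort size (19 canonical).
#' @param n_channels Number of sensor channels (8 default).
#' @param n_trials_per_condition Trials per condition per subject (8
#'   default).
#' @param fs Sampling rate in Hz (600 canonical).
#' @param epoch_window Epoch window in ms relative to stimulus onset
#'   (c(-250, 2550) canonical).
#' @param components Component table, see [default_component_table()].
#' @param noise_sd Scale of the 1/f sensor noise, in the same arbitrary
#'   units as the component amplitudes. The default (0.26) was calibrated
#'   once so that the evoked-to-total power ratio of the first DSS component
#'   is near 0.43 under the default cohort.
#' @param topo_overlap Fraction (0-1) of each component's topography that
#'   is a shared subject-level map (0.8 default). Evoked components of one
#'   subject arise from neighboring patches of auditory cortex, so their
#'   sensor maps overlap strongly; the shared map is what makes every
#'   component recoverable through a single DSS spatial filter.
#' @param subject_amp_sd Between-subject log-amplitude SD per component.
#' @param subject_lat_sd Between-subject latency jitter SD in ms.
#' @param seed Master integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 19,
                         n_channels = 8,
                         n_trials_per_condition = 8,
                         fs = 600,
                         epoch_window = c(-250, 2550),
                         components = default_component_table(),
                         noise_sd = 0.26,
                         topo_overlap = 0.8,
                         subject_amp_sd = 0.2,
                         subject_lat_sd = 5,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, n_channels >= 2, n_trials_per_condition >= 2,
            topo_overlap >= 0, topo_overlap <= 1)
  if (any(components$amplitude < 0)) {
    stop("Component amplitudes must be >= 0.", call. = FALSE)
  }
  structure(
    list(
      n_subjects = n_subjects, n_channels = n_channels,
      n_trials_per_condition = n_trials_per_condition, fs = fs,
      epoch_window = epoch_window, components = components,
      noise_sd = noise_sd, topo_overlap = topo_overlap,
      subject_amp_sd = subject_amp_sd,
      subject_lat_sd = subject_lat_sd, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# 1/f-shaped noise matrix (n_time x n_cols): white Gaussian noise spectrally
# reweighted by 1/sqrt(f) in the FFT domain (exact 1/f power, zero DC),
# rescaled so the whole matrix has unit SD
pink_noise_matrix <- function(n_time, n_cols) {
  # draw the spectrum directly: hermitian complex Gaussian with 1/sqrt(f)
  # amplitude, zero DC, one inverse FFT
  k <- seq_len(n_time) - 1L
  fidx <- pmin(k, n_time - k)
  a <- 1 / sqrt(pmax(fidx, 1))
  a[1] <- 0
  nh <- floor(n_time / 2)
  Zh <- matrix(complex(
    real = stats::rnorm(nh * n_cols),
    imaginary = stats::rnorm(nh * n_cols)
  ), nh, n_cols)
  if (n_time %% 2 == 0) Zh[nh, ] <- Re(Zh[nh, ])
  Z <- matrix(0i, n_time, n_cols)
  Z[2:(nh + 1), ] <- Zh
  Z[n_time:(n_time - nh + 2), ] <- Conj(Zh[seq_len(nh - 1), , drop = FALSE])
  y <- Re(stats::mvfft(Z * a, inverse = TRUE)) / n_time
  y / stats::sd(y)
}

# smooth random sensor topographies: channels on a Fibonacci sphere, maps
# drawn from a low-order polynomial (spherical-harmonic-like) basis
random_topographies <- function(n_channels, n_components) {
  i <- seq_len(n_channels) - 0.5
  z <- 1 - 2 * i / n_channels
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  xyz <- cbind(r * cos(th), r * sin(th), z)
  basis <- cbind(
    1, xyz,
    xyz[, 1] * xyz[, 2], xyz[, 2] * xyz[, 3], xyz[, 1] * xyz[, 3],
    xyz[, 1]^2 - xyz[, 2]^2, 3 * xyz[, 3]^2 - 1
  )
  w <- matrix(stats::rnorm(ncol(basis) * n_components), ncol(basis), n_components)
  topo <- basis %*% w
  sweep(topo, 2, sqrt(colSums(topo^2)), "/") * sqrt(n_channels)
}

anchor_time_ms <- function(anchor, sequence_order) {
  nr <- if (sequence_order == "NRN") 500 else 1400
  c(onset = 0, nr_transition = nr, offset = 2300)[[anchor]]
}

#' Simulate one subject's epochs for all 12 conditions
#'
#' Each trial is the sum over planted components of
#' `amplitude x Gaussian-windowed cosine` at the component's anchored
#' latency (with subject-specific amplitude and latency jitter), mixed into
#' channels through a smooth random topography that is fixed within the
#' subject, plus 1/f channel noise. Deterministic for a given
#' `(cfg$seed, subject_id)`.
#'
#' @param cfg A [synth_config()].
#' @param subject_id Positive integer subject index.
#' @return A tibble with one row per condition: design columns plus an
#'   `epochs` list-column of [epoch_array()] objects.
#' @export
simulate_subject <- function(cfg, subject_id) {
  stopifnot(inherits(cfg, "synth_config"), subject_id >= 1)
  subject_seed <- derive_seeds(cfg$seed, subject_id)[subject_id]
  comps <- dplyr::distinct(
    cfg$components,
    .data$component, .data$anchor, .data$latency_ms, .data$width_ms,
    .data$freq_hz
  )
  n_comp <- nrow(comps)
  n_time <- round(diff(cfg$epoch_window) / 1000 * cfg$fs)
  t_ms <- cfg$epoch_window[1] + (seq_len(n_time) - 1L) * 1000 / cfg$fs
  conds <- condition_table()

  n_tr <- cfg$n_trials_per_condition
  withr::with_seed(subject_seed, {
    shared <- random_topographies(cfg$n_channels, 1L)
    dev <- random_topographies(cfg$n_channels, n_comp)
    topo <- sqrt(cfg$topo_overlap) * shared[, rep(1L, n_comp)] +
      sqrt(1 - cfg$topo_overlap) * dev
    topo <- sweep(topo, 2, sqrt(colSums(topo^2)), "/") * sqrt(cfg$n_channels)
    amp_fac <- exp(stats::rnorm(n_comp, 0, cfg$subject_amp_sd))
    lat_jit <- stats::rnorm(n_comp, 0, cfg$subject_lat_sd)
    # one draw for all conditions; (trial x channel x time x condition)
    noise <- pink_noise_matrix(n_time, cfg$n_channels * n_tr * nrow(conds))
    dim(noise) <- c(n_time, cfg$n_channels, n_tr, nrow(conds))
    noise <- aperm(noise, c(3, 2, 1, 4)) * cfg$noise_sd
  })

  epochs <- purrr::pmap(conds, function(condition, stimulus_type, f0,
                                        sequence_order) {
    amps <- comps |>
      dplyr::left_join(
        dplyr::filter(cfg$components, .data$stimulus_type == !!stimulus_type,
                      .data$f0 == !!f0),
        by = c("component", "anchor", "latency_ms", "width_ms", "freq_hz")
      ) |>
      dplyr::pull(.data$amplitude)
    amps[is.na(amps)] <- 0
    # component time courses (n_comp x n_time), Gabor-like transients
    s <- vapply(seq_len(n_comp), function(k) {
      mu <- anchor_time_ms(comps$anchor[k], sequence_order) +
        comps$latency_ms[k] + lat_jit[k]
      a <- amps[k] * amp_fac[k]
      if (a == 0) return(numeric(n_time))
      a * exp(-(t_ms - mu)^2 / (2 * comps$width_ms[k]^2)) *
        cos(2 * pi * comps$freq_hz[k] * (t_ms - mu) / 1000)
    }, numeric(n_time))
    sig <- topo %*% t(s)                       # channel x time
    k <- which(conds$condition == condition)
    arr <- noise[, , , k] + aperm(
      array(sig, c(cfg$n_channels, n_time, n_tr)),
      c(3, 1, 2)
    )
    epoch_array(arr, fs = cfg$fs, t0 = cfg$epoch_window[1],
                condition = condition, subject = subject_id)
  })
  dplyr::mutate(conds, subject = subject_id, epochs = epochs, .before = 1)
}

#' Simulate a full cohort
#'
#' Runs [simulate_subject()] for `cfg$n_subjects` independent subjects
#' (independent per-subject seeds derived from the master seed; the same
#' master seed reproduces the identical cohort).
#'
#' @param cfg A [synth_config()].
#' @return A tibble with one row per (subject, condition): columns
#'   `subject`, `condition`, `stimulus_type`, `f0`, `sequence_order`,
#'   `epochs` (list of [epoch_array()]).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(cfg$n_subjects >= 2)
  purrr::map_dfr(seq_len(cfg$n_subjects), function(s) simulate_subject(cfg, s))
}
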