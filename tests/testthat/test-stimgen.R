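test_that("noise segments are zero-mean unit-variance and seed-deterministic", {
  w <- make_noise(0.5, 44100, seed = 1)
  expect_length(w$samples, 22050)
  expect_lt(abs(mean(w$samples)), 0.03)      # 4 sigma / sqrt(n) bound
  w2 <- make_noise(0.5, 44100, seed = 1)
  expect_identical(w$samples, w2$samples)
  for (s in 1:5) {
    v <- var(make_noise(0.9, 44100, seed = s)$samples)
    expect_gt(v, 0.95)
    expect_lt(v, 1.05)
  }
  expect_error(make_noise(-1, 44100, 1), "duration")
  expect_error(make_noise(1, -44100, 1), "fs")
})

test_that("harmonic complexes have all and only harmonics up to Nyquist", {
  w <- make_harmonic_complex(250, 1.0, 44100)   # 1-s window -> 1-Hz bins
  spec <- abs(fft(w$samples))[1:22050]
  freq <- (0:22049)
  peak_amp <- max(spec)
  harm_bins <- 250 * (1:88) + 1
  expect_true(all(spec[harm_bins] > peak_amp / 100))
  # count spectral lines above -40 dB of max: exactly the 88 partials
  lines <- which(spec > peak_amp * 10^(-40 / 20))
  expect_equal(sum((lines - 1) %% 250 == 0 & lines > 1), 88)
  expect_true(all((lines - 1) %% 250 == 0))
  # no energy between harmonics
  expect_lt(spec[376], peak_amp / 100)
  expect_error(make_harmonic_complex(30000, 0.1, 44100), "Nyquist")
})

test_that("Schroeder phase lowers the crest factor relative to zero phase", {
  cf_s <- crest_factor(make_harmonic_complex(250, 0.9, 44100))
  cf_0 <- crest_factor(make_harmonic_complex(250, 0.9, 44100, phase = "zero"))
  expect_lt(cf_s, cf_0)
  cf_neg <- crest_factor(
    make_harmonic_complex(250, 0.9, 44100, schroeder_sign = -1)
  )
  expect_lt(cf_neg, cf_0)
})

test_that("click trains place single-sample unit impulses at multiples of the period", {
  ct <- make_click_train(20, 0.9, 44100)
  idx <- which(ct$samples != 0)
  expect_length(idx, 18)                        # ceil(0.9 * 20)
  expect_true(all(ct$samples[idx] == 1))
  expect_equal(unique(diff(idx)), 2205)         # 50 ms at 44.1 kHz
  ct250 <- make_click_train(250, 0.9, 44100)
  expect_equal(sum(ct250$samples != 0), 225)
  expect_error(make_click_train(30000, 0.1, 44100), "too high")
})

test_that("iterated delay-and-add imposes an autocorrelation peak at 1/F0", {
  # zero iterations is the identity on the base noise
  x0 <- make_rin(250, 0.9, 44100, iterations = 0, seed = 4)
  expect_identical(x0$samples, make_noise(0.9, 44100, seed = 4)$samples)

  lag <- round(44100 / 250)
  gain <- sapply(1:20, function(s) {
    r <- make_rin(250, 0.9, 44100, 16, 1, seed = s)
    n <- make_noise(0.9, 44100, seed = s + 1000)
    acf_at_lag(r$samples, lag) - acf_at_lag(n$samples, lag)
  })
  expect_gt(mean(gain), 0.3)

  # the peak at 1/F0 is the global ACF maximum between half and two periods
  r <- make_rin(250, 0.9, 44100, 16, 1, seed = 7)
  lags <- seq(round(lag / 2), 2 * lag)
  acfs <- sapply(lags, function(l) acf_at_lag(r$samples, l))
  expect_equal(lags[which.max(acfs)], lag)

  # add-original variant shows the same regularity marker
  r2 <- make_rin(250, 0.9, 44100, 16, 1, seed = 7, variant = "add_original")
  expect_gt(acf_at_lag(r2$samples, lag), 0.3)
})

test_that("maskers cover 0.5-1.5 F0 with 2nd-order Butterworth skirts", {
  m <- make_masker(250, 10, 44100, seed = 2)
  psd <- psd_welch(m)
  in_band <- band_power(psd, 125, 375) /
    sum(psd$freq >= 125 & psd$freq <= 375)
  at_4f0 <- band_power(psd, 990, 1010) / sum(psd$freq >= 990 & psd$freq <= 1010)
  expect_gt(db10(in_band, at_4f0), 20)
  m20 <- make_masker(20, 10, 44100, seed = 2)
  psd20 <- psd_welch(m20, seg_len = 16384)
  expect_gt(
    db10(
      band_power(psd20, 10, 30) / 8,
      band_power(psd20, 75, 85) / 4
    ),
    20
  )
  expect_error(make_masker(20000, 1, 44100, 1), "Nyquist")
})

test_that("stimulus bandpass attenuates out-of-band energy, passes the band", {
  wn <- make_noise(10, 44100, seed = 3)
  bp <- butterworth_bandpass(wn, 1000, 4000, order = 4)
  psd <- psd_welch(bp)
  p500 <- band_power(psd, 480, 520) / 5
  p2000 <- band_power(psd, 1980, 2020) / 5
  expect_gt(db10(p2000, p500), 20)
  # zero in, zero out
  z <- butterworth_bandpass(waveform(numeric(1000), 44100), 1000, 4000)
  expect_true(all(z$samples == 0))
  # 2 kHz tone passes within 1 dB
  t <- seq(0, 1, by = 1 / 44100)
  tone <- waveform(sin(2 * pi * 2000 * t), 44100)
  out <- butterworth_bandpass(tone, 1000, 4000, order = 4)
  mid <- 2000:42000
  expect_lt(abs(db10(mean(out$samples[mid]^2), mean(tone$samples[mid]^2))), 1)
  expect_error(butterworth_bandpass(wn, 4000, 1000), "Band edges")
})

test_that("pink shaping imposes a 1/f power slope and is linear", {
  wn <- make_noise(20, 44100, seed = 8)
  pk <- pink_shape(wn)
  psd <- psd_welch(pk)
  sel <- psd$freq >= 100 & psd$freq <= 10000
  fit <- stats::lm(log(psd$power[sel]) ~ log(psd$freq[sel]))
  expect_lt(abs(stats::coef(fit)[2] + 1), 0.15)
  # cascading doubles the slope
  pk2 <- pink_shape(pk)
  psd2 <- psd_welch(pk2)
  fit2 <- stats::lm(log(psd2$power[sel]) ~ log(psd2$freq[sel]))
  expect_lt(abs(stats::coef(fit2)[2] + 2), 0.3)
  z <- pink_shape(waveform(numeric(4096), 44100))
  expect_lt(max(abs(z$samples)), 1e-12)
})

test_that("assembled sequences have the canonical duration, ramps and layout", {
  spec <- stimulus_spec("CT", 250, "NRN", seed = 21)
  w <- assemble_sequence(spec)
  expect_length(w$samples, round(2.3 * 44100))
  expect_identical(w$samples[1], 0)
  expect_identical(w$samples[length(w$samples)], 0)
  # determinism
  expect_identical(w$samples, assemble_sequence(spec)$samples)

  # regularity is confined to the regular segment: windowed ACF around the
  # 1/F0 lag (176.4 samples, so the peak spreads over adjacent integer lags)
  expect_gt(acf_period(w, 0.6, 1.3), acf_period(w, 0.05, 0.45))
  expect_gt(acf_period(w, 0.6, 1.3), acf_period(w, 1.5, 2.25))
})

test_that("the regularity marker separates segments across seeded trials and types", {
  for (type in c("HC", "CT", "RIN")) {
    n_seeds <- if (type == "CT") 20 else 5
    ok <- vapply(seq_len(n_seeds), function(s) {
      w <- assemble_sequence(stimulus_spec(type, 250, "NRN", seed = 100 + s))
      acf_period(w, 0.6, 1.3) > max(
        acf_period(w, 0.05, 0.45), acf_period(w, 1.5, 2.25)
      )
    }, TRUE)
    expect_true(all(ok))
  }
})

test_that("regular segment types share segment lengths and the RNR order flips them", {
  for (type in c("HC", "CT", "RIN")) {
    w <- assemble_sequence(stimulus_spec(type, 250, "NRN", seed = 3))
    expect_length(w$samples, round(2.3 * 44100))
  }
  # RNR: regularity in first and last segments
  w <- assemble_sequence(stimulus_spec("CT", 250, "RNR", seed = 9))
  expect_gt(acf_period(w, 0.05, 0.45), acf_period(w, 0.6, 1.3))
  expect_gt(acf_period(w, 1.5, 2.25), acf_period(w, 0.6, 1.3))
})

test_that("assembled power is contained in the masker-to-passband range", {
  for (s in c(1, 2)) {
    w <- assemble_sequence(stimulus_spec("HC", 250, "NRN", seed = s))
    psd <- psd_welch(w)
    expect_gt(
      band_power(psd, 0.5 * 125, 4500) / sum(psd$power),
      0.90
    )
  }
})

test_that("session manifests enumerate the factorial design with jittered ISIs", {
  m <- build_manifest(n_reps = 60, seed = 5)
  expect_equal(nrow(m), 720)
  counts <- dplyr::count(m, stimulus_type, f0, sequence_order)
  expect_equal(nrow(counts), 12)
  expect_true(all(counts$n == 60))
  expect_true(all(m$isi_ms >= 900 & m$isi_ms <= 1100))
  expect_lt(abs(mean(m$isi_ms) - 1000), 5)
  expect_equal(length(unique(m$trial_seed)), 720)
  expect_identical(m, build_manifest(n_reps = 60, seed = 5))

  m1 <- build_manifest(n_reps = 1, seed = 1)
  expect_equal(nrow(m1), 12)
  expect_equal(nrow(dplyr::distinct(m1[, 2:4])), 12)
})

test_that("manifest and WAV round-trip through their file formats", {
  m <- build_manifest(n_reps = 1, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_equal(as.data.frame(m2), as.data.frame(m))

  w <- assemble_sequence(stimulus_spec("RIN", 20, "NRN", seed = 2))
  wav <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, wav)
  rt <- read_wav(wav)
  expect_equal(rt$fs, 44100)
  expect_equal(rt$samples, w$samples, tolerance = 1e-3)
  expect_equal(
    stimulus_filename("HC", 250, "NRN", 3), "HC250NRN_0003.wav"
  )
})

test_that("stimulus configs round-trip through the key-value file", {
  spec <- stimulus_spec("RIN", 20, "RNR", masker_gain = 0.2, seed = 17)
  path <- withr::local_tempfile(fileext = ".yml")
  write_stimulus_config(spec, path)
  spec2 <- read_stimulus_config(path)
  expect_equal(spec2, spec)
  expect_identical(
    assemble_sequence(spec2)$samples, assemble_sequence(spec)$samples
  )
})
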