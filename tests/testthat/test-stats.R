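test_that("rm_anova matches the aov Error-stratum oracle on small designs", {
  designs <- list(
    tibble::tibble(
      condition = c("a1", "a2", "b1", "b2"),
      A = rep(c("a", "b"), each = 2), B = rep(c("1", "2"), 2)
    ),
    tibble::tibble(
      condition = paste0(rep(c("a", "b", "c"), each = 2), 1:2),
      A = rep(c("a", "b", "c"), each = 2), B = rep(c("1", "2"), 3)
    )
  )
  for (design in designs) {
    for (n_s in 3:5) {
      y <- withr::with_seed(n_s * 10 + nrow(design), {
        array(rnorm(n_s * nrow(design) * 2), c(n_s, nrow(design), 2),
              dimnames = list(NULL, design$condition, NULL))
      })
      res <- rm_anova(y, design)
      for (smp in 1:2) {
        oracle <- aov_oracle(y[, , smp], design)
        expect_equal(
          res$F[res$effect == "A" & res$sample == smp], oracle[["A"]],
          tolerance = 1e-10
        )
        expect_equal(
          res$F[res$effect == "B" & res$sample == smp], oracle[["B"]],
          tolerance = 1e-10
        )
        expect_equal(
          res$F[res$effect == "A:B" & res$sample == smp], oracle[["A:B"]],
          tolerance = 1e-10
        )
      }
    }
  }
})

test_that("two-level main effect F equals the squared paired t statistic", {
  design <- tibble::tibble(condition = c("lo", "hi"), A = c("lo", "hi"))
  y <- withr::with_seed(4, array(rnorm(5 * 2 * 3), c(5, 2, 3),
                                 dimnames = list(NULL, design$condition, NULL)))
  res <- rm_anova(y, design)
  for (smp in 1:3) {
    tt <- stats::t.test(y[, 1, smp], y[, 2, smp], paired = TRUE)$statistic
    expect_equal(res$F[res$sample == smp], unname(tt^2), tolerance = 1e-10)
  }
  expect_equal(unique(res$df1), 1)
  expect_equal(unique(res$df2), 4)
})

test_that("degenerate and malformed inputs are rejected or zeroed", {
  design <- tibble::tibble(condition = c("a", "b"), A = c("a", "b"))
  same <- array(rep(c(1, 2, 3), each = 2), c(3, 2, 1),
                dimnames = list(NULL, design$condition, NULL))
  same <- aperm(same, c(3, 1, 2))              # wrong orientation on purpose
  y <- array(0, c(3, 2, 1), dimnames = list(NULL, design$condition, NULL))
  y[, 1, 1] <- c(1, 2, 3)
  y[, 2, 1] <- c(1, 2, 3)                      # identical per subject
  expect_equal(rm_anova(y, design)$F, 0)
  bad <- tibble::tibble(condition = c("a", "b", "c"), A = c("a", "b", "b"))
  expect_error(rm_anova(y, bad), "balanced|match")
  expect_error(rm_anova(y[1, , , drop = FALSE], design), "2 subjects")
  expect_error(rm_anova(y, design, effects = "nope"), "Unknown factor")
})

test_that("long data frames and arrays give identical F maps", {
  design <- design_2x3()
  y <- withr::with_seed(2, array(rnorm(4 * 6 * 5), c(4, 6, 5),
                                 dimnames = list(NULL, design$condition, NULL)))
  long <- tidyr::expand_grid(subject = 1:4, condition = design$condition,
                             sample = 1:5) |>
    dplyr::mutate(value = purrr::pmap_dbl(
      list(subject, condition, sample),
      function(s, cn, smp) y[s, which(design$condition == cn), smp]
    ))
  expect_equal(rm_anova(long, design), rm_anova(y, design))
})

test_that("F thresholds are the upper-tail F quantiles", {
  expect_equal(f_threshold(0.5, 1, 1), 1.0, tolerance = 1e-12)
  # F(1, 18) upper 0.1% point, cross-checked against the square of the
  # two-sided t(18) critical value: qt(1 - 5e-4, 18)^2
  expect_equal(f_threshold(0.001, 1, 18), stats::qt(1 - 5e-4, 18)^2,
               tolerance = 1e-10)
  expect_equal(f_threshold(0.001, 1, 18), 15.379, tolerance = 1e-3)
  expect_gt(f_threshold(0.001, 2, 10), f_threshold(0.01, 2, 10))
  expect_error(f_threshold(1.2, 1, 10), "0, 1")
})

test_that("temporal clusters are contiguous suprathreshold runs with F mass", {
  cl <- find_clusters(c(0, 5, 6, 0, 7), threshold = 4)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$mass, c(11, 7))
  expect_equal(cl$members[[1]], 2:3)
  expect_equal(nrow(find_clusters(rep(0, 10), 4)), 0)
})

test_that("spatiotemporal clusters follow mesh plus temporal adjacency", {
  mesh <- make_toy_mesh(0)                    # 12 vertices
  f <- matrix(0, 12, 4)
  f[3, 2] <- 5
  f[3, 3] <- 6                                # same vertex, adjacent times
  cl <- find_clusters(f, 4, adjacency = mesh)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_samples, 2)
  expect_equal(cl$mass, 11)

  # two vertices joined only if they share a mesh edge at the same time
  nbr_of <- function(v) {
    unique(c(mesh$edges[mesh$edges[, 1] == v, 2],
             mesh$edges[mesh$edges[, 2] == v, 1]))
  }
  nb <- nbr_of(1)[1]
  far <- setdiff(1:12, c(1, nbr_of(1), nbr_of(nb)))[1]
  f2 <- matrix(0, 12, 1)
  f2[c(1, nb, far), 1] <- 5
  cl2 <- find_clusters(f2, 4, adjacency = mesh)
  expect_equal(sort(cl2$n_samples), c(1, 2))
})

test_that("permutation p-values respect the add-one floor and reproduce", {
  design <- design_2x3()
  y <- withr::with_seed(3, {
    a <- array(rnorm(8 * 6 * 40), c(8, 6, 40),
               dimnames = list(NULL, design$condition, NULL))
    a[, design$f0 == 250, 15:20] <- a[, design$f0 == 250, 15:20] + 2
    a
  })
  r <- cluster_permutation_test(y, design, "f0", n_perm = 200, seed = 5)
  expect_true(all(r$clusters$p_value >= 1 / 201))
  expect_true(all(r$clusters$p_value <= 1))
  r2 <- cluster_permutation_test(y, design, "f0", n_perm = 200, seed = 5)
  expect_identical(r$clusters$p_value, r2$clusters$p_value)
  expect_identical(r$null_max, r2$null_max)
  # the planted window is detected
  expect_lt(min(r$clusters$p_value), 0.05)
  sig <- r$clusters[which.min(r$clusters$p_value), ]
  expect_true(any(15:20 %in% sig$members[[1]]))
})

test_that("the null max-mass distribution is invariant to the observed labeling", {
  design <- design_2x3()
  y <- withr::with_seed(8, array(rnorm(10 * 6 * 60), c(10, 6, 60),
                                 dimnames = list(NULL, design$condition, NULL)))
  r1 <- cluster_permutation_test(y, design, "f0", n_perm = 400, seed = 1)
  r2 <- cluster_permutation_test(y, design, "f0", n_perm = 400, seed = 2)
  ks <- suppressWarnings(stats::ks.test(r1$null_max, r2$null_max))
  expect_gt(ks$p.value, 0.01)
})

test_that("restricted permutation shuffles only within the off-effect strata", {
  design <- design_2x3()
  blocks <- pitchonset:::permutation_blocks(
    design, c("stimulus_type", "f0"), "f0", "restricted"
  )
  expect_equal(length(blocks), 3)             # one block per stimulus type
  expect_true(all(lengths(blocks) == 2))
  full <- pitchonset:::permutation_blocks(
    design, c("stimulus_type", "f0"), "f0", "full"
  )
  expect_equal(full, list(1:6))
  y <- withr::with_seed(9, array(rnorm(8 * 6 * 30), c(8, 6, 30),
                                 dimnames = list(NULL, design$condition, NULL)))
  r <- cluster_permutation_test(y, design, "f0", n_perm = 100, seed = 3,
                                scheme = "restricted")
  expect_s3_class(r, "cluster_result")
})

test_that("detection rate grows monotonically with the planted amplitude", {
  design <- design_2x3()
  amps <- c(0.3, 0.8, 1.6)
  rates <- vapply(amps, function(a) {
    mean(vapply(1:40, function(r) {
      y <- withr::with_seed(r + a * 1000, {
        arr <- array(rnorm(8 * 6 * 60), c(8, 6, 60),
                     dimnames = list(NULL, design$condition, NULL))
        arr[, design$f0 == 250, 25:30] <- arr[, design$f0 == 250, 25:30] + a
        arr
      })
      ct <- cluster_permutation_test(y, design, "f0", n_perm = 150, seed = r)
      nrow(ct$clusters) > 0 && min(ct$clusters$p_value) <= 0.05
    }, TRUE))
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("spatiotemporal permutation path matches its own contract", {
  mesh <- make_toy_mesh(0)
  design <- tibble::tibble(condition = c("lo", "hi"), A = c("lo", "hi"))
  n_times <- 5
  y <- withr::with_seed(6, {
    arr <- array(rnorm(8 * 2 * 12 * n_times), c(8, 2, 12 * n_times),
                 dimnames = list(NULL, design$condition, NULL))
    # plant an effect at vertex 4, times 2:4 (flattened vertex-fastest)
    idx <- 4 + 12 * (1:3)
    arr[, 2, idx] <- arr[, 2, idx] + 6
    arr
  })
  r <- cluster_permutation_test(y, design, "A", n_perm = 100,
                                adjacency = mesh, n_times = n_times, seed = 2)
  expect_gt(nrow(r$clusters), 0)
  best <- r$clusters$members[[which.min(r$clusters$p_value)]]
  expect_true(all((4 + 12 * (1:3)) %in% best))
  expect_lt(min(r$clusters$p_value), 0.05)
})

test_that("Holm correction reproduces the step-down thresholds", {
  h <- holm_correct(c(a = 0.001, b = 0.0462, c = 0.30))
  expect_equal(h$step_alpha[h$rank == 1], 0.05 / 3, tolerance = 1e-12)
  expect_equal(round(h$step_alpha[h$rank == 1], 4), 0.0167)
  expect_true(h$significant[h$contrast == "a"])
  expect_false(h$significant[h$contrast == "c"])
  # 0.0462 exceeds its own step threshold (0.025), so the step-down stops
  expect_false(h$significant[h$contrast == "b"])
  # and as the smallest p of a 3-contrast family it misses the 0.0167 bar
  h2 <- holm_correct(c(0.0462, 0.7, 0.9))
  expect_false(any(h2$significant))
  expect_equal(h2$adjusted_p, stats::p.adjust(c(0.0462, 0.7, 0.9), "holm"))
  h1 <- holm_correct(0.04)
  expect_true(h1$significant)
  expect_equal(h1$step_alpha, 0.05)
})

test_that("autocorrelation peaks sit at the stimulus period lags", {
  fs <- 600
  t <- seq_len(900) / fs
  per <- sin(2 * pi * 20 * t)                  # 50-ms period
  pk <- autocorr_peaks(per, candidate_lags_ms = 50, fs = fs)
  expect_equal(pk$peak_lag_ms, 50, tolerance = 1e-9)
  expect_gt(pk$prominence, 0.5)

  # white noise: no prominent peak at the candidate lags
  prom <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rnorm(900))
    p <- autocorr_peaks(x, 50, fs = fs)
    if (is.na(p$prominence)) 0 else p$prominence
  }, 0)
  expect_lt(stats::median(prom), 0.2)
  expect_error(autocorr_peaks(per[1:50], 200, fs = fs), "half the signal")
})

test_that("cluster reports export to JSON and CSV", {
  design <- design_2x3()
  y <- withr::with_seed(3, {
    a <- array(rnorm(8 * 6 * 40), c(8, 6, 40),
               dimnames = list(NULL, design$condition, NULL))
    a[, design$f0 == 250, 15:20] <- a[, design$f0 == 250, 15:20] + 2
    a
  })
  r <- cluster_permutation_test(y, design, "f0", n_perm = 100, seed = 5)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  tab <- write_cluster_report(r, jp, cp, times_ms = seq(-200, 190, by = 10))
  expect_true(file.exists(jp) && file.exists(cp))
  js <- jsonlite::read_json(jp)
  expect_equal(js$effect, "f0")
  expect_equal(length(js$clusters), nrow(r$clusters))   # one object per cluster
  expect_true(all(c("mass", "p_value") %in% names(js$clusters[[1]])))
  csv <- readr::read_csv(cp, show_col_types = FALSE)
  expect_equal(nrow(csv), nrow(r$clusters))
  expect_true(all(c("mass", "p_value", "start_ms") %in% names(csv)))
})
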