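#' Mass-univariate repeated-measures ANOVA
#'
#' Classical within-subject F tests computed independently at every sample
#' of a (subject x condition x sample) array with one value per cell
#' (condition means per subject). For each requested effect, the F statistic
#' is `MS_effect / MS_(effect x subject)`, the standard univariate
#' partitioning for balanced fully-crossed within-subject designs; 2-way
#' (3 effects) and 3-way (7 effects) designs are supported, and no
#' sphericity correction is applied (the sample-wise F is a cluster-forming
#' heuristic downstream).
#'
#' @param data A 3-D numeric array (subject x condition x sample). If the
#'   second dimension carries dimnames they are matched against
#'   `design$condition`; otherwise the order of `design` rows is assumed.
#'   Alternatively a long tibble with columns `subject`, `condition`,
#'   `sample`, `value`.
#' @param design A tibble with a `condition` column plus one column per
#'   within-subject factor (e.g. `stimulus_type`, `f0`), one row per
#'   condition, fully crossed and balanced.
#' @param effects Character vector of effects, factor names joined by `:`
#'   for interactions (e.g. `c("f0", "stimulus_type", "f0:stimulus_type")`).
#'   Defaults to all main effects and interactions.
#' @return A tibble with columns `effect`, `sample`, `F`, `df1`, `df2`.
#' @examples
#' design <- tibble::tibble(
#'   condition = c("a1", "a2", "b1", "b2"),
#'   A = c("a", "a", "b", "b"), B = c("1", "2", "1", "2")
#' )
#' y <- array(rnorm(5 * 4 * 3), c(5, 4, 3),
#'            dimnames = list(NULL, design$condition, NULL))
#' rm_anova(y, design)
#' @export
rm_anova <- function(data, design, effects = NULL) {
  prep <- rm_prepare(data, design, effects)
  out <- purrr::map_dfr(prep$effects, function(eff) {
    pe <- prep$proj[[eff]]
    f <- f_from_cts(prep$Y, pe$A, pe$df1, pe$df2)
    tibble::tibble(
      effect = eff, sample = seq_along(f), F = f,
      df1 = pe$df1, df2 = pe$df2
    )
  })
  out
}

# ---- internals shared with the permutation test ----

# reshape + validate into (condition x sample x subject) array plus
# projection matrices per effect
rm_prepare <- function(data, design, effects = NULL) {
  stopifnot(is.data.frame(design), "condition" %in% names(design))
  factors <- setdiff(names(design), "condition")
  if (length(factors) < 1L) stop("`design` needs at least one factor column.", call. = FALSE)
  levels_per <- lapply(design[factors], function(col) sort(unique(col)))
  n_expected <- prod(lengths(levels_per))
  if (nrow(design) != n_expected ||
      nrow(dplyr::distinct(design[factors])) != nrow(design)) {
    stop("`design` must be balanced and fully crossed (every cell once).",
         call. = FALSE)
  }
  arr <- as_rm_array(data, design)
  n_s <- dim(arr)[1]
  if (n_s < 2L) stop("At least 2 subjects are required.", call. = FALSE)
  if (anyNA(arr)) stop("Missing cells in the design.", call. = FALSE)
  Y <- aperm(arr, c(2, 3, 1))                   # condition x sample x subject

  if (is.null(effects)) {
    effects <- unlist(lapply(seq_along(factors), function(k) {
      utils::combn(factors, k, paste, collapse = ":", simplify = FALSE)
    }))
  }
  H <- lapply(factors, function(f) averaging_operator(design, factors, f))
  names(H) <- factors
  n_c <- nrow(design)
  proj <- lapply(effects, function(eff) {
    in_eff <- strsplit(eff, ":", fixed = TRUE)[[1]]
    if (!all(in_eff %in% factors)) {
      stop(sprintf("Unknown factor in effect '%s'.", eff), call. = FALSE)
    }
    A <- diag(n_c)
    for (f in factors) {
      A <- if (f %in% in_eff) A %*% (diag(n_c) - H[[f]]) else A %*% H[[f]]
    }
    df1 <- prod(vapply(in_eff, function(f) length(levels_per[[f]]) - 1L, 1L))
    list(A = A, df1 = df1, df2 = df1 * (n_s - 1L))
  })
  names(proj) <- effects
  list(Y = Y, proj = proj, effects = effects, design = design,
       factors = factors, n_subjects = n_s)
}

# averaging operator over factor f holding all other factors fixed
averaging_operator <- function(design, factors, f) {
  others <- setdiff(factors, f)
  n_c <- nrow(design)
  same <- matrix(TRUE, n_c, n_c)
  for (g in others) {
    same <- same & outer(design[[g]], design[[g]], "==")
  }
  l_f <- length(unique(design[[f]]))
  same / l_f
}

as_rm_array <- function(data, design) {
  if (is.array(data) && length(dim(data)) == 3L) {
    cn <- dimnames(data)[[2]]
    if (!is.null(cn)) {
      if (!setequal(cn, design$condition)) {
        stop("Array condition names do not match the design.", call. = FALSE)
      }
      data <- data[, match(design$condition, cn), , drop = FALSE]
    } else if (dim(data)[2] != nrow(design)) {
      stop("Condition dimension does not match the design.", call. = FALSE)
    }
    return(data)
  }
  if (is.data.frame(data)) {
    need <- c("subject", "condition", "sample", "value")
    stopifnot(all(need %in% names(data)))
    subjects <- sort(unique(data$subject))
    samples <- sort(unique(data$sample))
    arr <- array(NA_real_,
      c(length(subjects), nrow(design), length(samples)),
      dimnames = list(NULL, design$condition, NULL)
    )
    arr[cbind(
      match(data$subject, subjects),
      match(data$condition, design$condition),
      match(data$sample, samples)
    )] <- data$value
    return(arr)
  }
  stop("`data` must be a 3-D array or a long data frame.", call. = FALSE)
}

# F per sample from the (condition x sample x subject) array; single BLAS
# multiply so it is cheap inside the permutation loop
f_from_cts <- function(Y, A, df1, df2) {
  d <- dim(Y)
  AY <- A %*% matrix(Y, d[1])
  dim(AY) <- d
  M <- rowMeans(AY, dims = 2)                  # A applied to the subject mean
  ss_eff <- d[3] * colSums(M^2)
  ss_all <- rowSums(colSums(AY^2))
  ss_err <- pmax(ss_all - ss_eff, 0)
  f <- (ss_eff / df1) / (ss_err / df2)
  f[ss_eff == 0] <- 0                          # no effect variance -> F = 0
  f
}

#' Cluster-forming F threshold
#'
#' Upper-tail quantile of the F distribution: the sample-wise F value whose
#' parametric p equals `p` for the given degrees of freedom.
#'
#' @param p Upper-tail probability (0.001 canonical).
#' @param df1,df2 Effect and error degrees of freedom.
#' @return The F threshold.
#' @examples
#' f_threshold(0.001, 1, 18)
#' @export
f_threshold <- function(p, df1, df2) {
  if (!(p > 0 && p < 1)) stop("`p` must lie in (0, 1).", call. = FALSE)
  if (df1 < 1 || df2 < 1) stop("Degrees of freedom must be positive.", call. = FALSE)
  stats::qf(1 - p, df1, df2)
}
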