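#' Find suprathreshold clusters of a statistic map
#'
#' Temporal maps (a numeric vector over samples) form clusters as maximal
#' contiguous runs above threshold. Spatiotemporal maps (a vertex x time
#' matrix plus a mesh adjacency) form clusters as connected components of
#' the graph whose edges join suprathreshold samples that share a mesh edge
#' at the same time point, or the same vertex at adjacent time points (no
#' adjacency across separate meshes). The cluster statistic is the mass:
#' the sum of the statistic over the cluster's samples.
#'
#' @param f Numeric vector (temporal) or vertex x time matrix
#'   (spatiotemporal) of sample-wise F values.
#' @param threshold Cluster-forming threshold (e.g. from [f_threshold()]).
#' @param adjacency A `mesh_graph` from [make_toy_mesh()]; required when
#'   `f` is a matrix.
#' @return A tibble with one row per cluster: `cluster`, `mass`,
#'   `n_samples`, and `members` (a list of sample indices into `f`; for
#'   matrices, indices into the flattened vertex x time array).
#' @export
find_clusters <- function(f, threshold, adjacency = NULL) {
  stopifnot(threshold > 0)
  if (is.matrix(f)) {
    if (is.null(adjacency)) {
      stop("Spatiotemporal clustering needs a mesh `adjacency`.", call. = FALSE)
    }
    return(find_clusters_st(f, threshold, adjacency))
  }
  above <- which(f > threshold)
  if (length(above) == 0L) {
    return(tibble::tibble(
      cluster = integer(), mass = numeric(), n_samples = integer(),
      members = list()
    ))
  }
  grp <- cumsum(c(1L, diff(above) != 1L))
  members <- unname(split(above, grp))
  tibble::tibble(
    cluster = seq_along(members),
    mass = vapply(members, function(i) sum(f[i]), 0),
    n_samples = lengths(members),
    members = members
  )
}

# connected components over the vertex x time lattice via union-find
find_clusters_st <- function(f, threshold, adjacency) {
  nv <- nrow(f)
  nt <- ncol(f)
  if (adjacency$n_vertices != nv) {
    stop("Mesh size does not match the vertex dimension of `f`.", call. = FALSE)
  }
  above <- f > threshold
  idx <- which(above)
  empty <- tibble::tibble(
    cluster = integer(), mass = numeric(), n_samples = integer(),
    members = list()
  )
  if (length(idx) == 0L) return(empty)
  parent <- seq_along(idx)
  pos <- integer(nv * nt)
  pos[idx] <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  # same vertex, adjacent times
  tmp <- idx[idx <= nv * (nt - 1L)]
  tmp <- tmp[above[tmp + nv]]
  for (i in tmp) unite(pos[i], pos[i + nv])
  # mesh edge, same time
  e <- adjacency$edges
  for (t in seq_len(nt)) {
    off <- (t - 1L) * nv
    keep <- above[e[, 1] + off] & above[e[, 2] + off]
    if (any(keep)) {
      ek <- e[keep, , drop = FALSE]
      for (r in seq_len(nrow(ek))) {
        unite(pos[ek[r, 1] + off], pos[ek[r, 2] + off])
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 1L)
  members <- unname(split(idx, roots))
  tibble::tibble(
    cluster = seq_along(members),
    mass = vapply(members, function(i) sum(f[i]), 0),
    n_samples = lengths(members),
    members = members
  )
}

# max cluster mass of a temporal F series (fast path for permutations)
max_cluster_mass <- function(f, threshold) {
  above <- which(f > threshold)
  if (length(above) == 0L) return(0)
  grp <- cumsum(c(1L, diff(above) != 1L))
  max(rowsum(f[above], grp))
}

max_cluster_mass_st <- function(f, threshold, adjacency) {
  cl <- find_clusters_st(f, threshold, adjacency)
  if (nrow(cl) == 0L) 0 else max(cl$mass)
}

#' Cluster-based permutation test for one RM-ANOVA effect
#'
#' Mass-univariate F values for the requested effect are thresholded at the
#' parametric `threshold_p` quantile (the cluster-forming threshold);
#' suprathreshold clusters are scored by their mass and compared against the
#' permutation null distribution of the *maximum* cluster mass, obtained by
#' shuffling condition labels independently within each subject
#' (synchronized across samples). Cluster p-values use the add-one
#' estimator `p = (1 + #{perm max-mass >= observed}) / (1 + n_perm)`, so
#' they are never exactly zero and never below `1 / (n_perm + 1)`.
#'
#' The default scheme shuffles all condition labels within subject for
#' every effect, including interactions (an approximate interaction null);
#' `scheme = "restricted"` permutes only the levels of the tested factors
#' within each combination of the remaining factors.
#'
#' @inheritParams rm_anova
#' @param effect A single effect name (see [rm_anova()]).
#' @param threshold_p Cluster-forming parametric p (0.001 canonical).
#' @param n_perm Number of permutations (10000 canonical).
#' @param adjacency Optional `mesh_graph` for spatiotemporal data; when
#'   supplied, `data`'s sample dimension must be the flattened
#'   vertex x time array (vertex varying fastest) and `n_times` must be
#'   given.
#' @param n_times Number of time points for spatiotemporal data.
#' @param scheme `"full"` (default) or `"restricted"` label shuffling.
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `cluster_result`: the observed cluster tibble
#'   (`cluster`, `mass`, `n_samples`, `members`, `p_value`) plus the test
#'   metadata and the permutation null distribution.
#' @export
cluster_permutation_test <- function(data, design, effect,
                                     threshold_p = 0.001,
                                     n_perm = 10000,
                                     adjacency = NULL,
                                     n_times = NULL,
                                     scheme = c("full", "restricted"),
                                     seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1)
  prep <- rm_prepare(data, design, effects = effect)
  pe <- prep$proj[[effect]]
  thr <- f_threshold(threshold_p, pe$df1, pe$df2)
  Y <- prep$Y
  d <- dim(Y)
  spatiotemporal <- !is.null(adjacency)
  if (spatiotemporal) {
    if (is.null(n_times) || d[2] %% n_times != 0) {
      stop("Spatiotemporal data needs `n_times` dividing the sample count.",
           call. = FALSE)
    }
    nv <- d[2] / n_times
    if (nv != adjacency$n_vertices) {
      stop("Mesh size does not match the data.", call. = FALSE)
    }
  }

  as_map <- function(fvec) {
    if (spatiotemporal) matrix(fvec, ncol = n_times) else fvec
  }
  f_obs <- f_from_cts(Y, pe$A, pe$df1, pe$df2)
  obs <- find_clusters(as_map(f_obs), thr, adjacency)

  perm_sets <- permutation_blocks(prep$design, prep$factors, effect, scheme)
  null_max <- if (spatiotemporal) {
    withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        Yp <- Y
        for (s in seq_len(d[3])) {
          perm <- seq_len(d[1])
          for (blk in perm_sets) perm[blk] <- blk[sample.int(length(blk))]
          Yp[, , s] <- Y[perm, , s]
        }
        fp <- f_from_cts(Yp, pe$A, pe$df1, pe$df2)
        max_cluster_mass_st(as_map(fp), thr, adjacency)
      }, 0)
    })
  } else {
    perms <- withr::with_seed(
      seed, draw_permutations(d[1], n_perm * d[3], perm_sets)
    )
    # orthonormal contrast rows spanning the effect subspace: A = t(Cm) Cm
    ea <- eigen(pe$A, symmetric = TRUE)
    Cm <- t(ea$vectors[, ea$values > 0.5, drop = FALSE])
    stopifnot(nrow(Cm) == pe$df1)
    perm_null_max_mass(Y, Cm, perms, n_perm, thr, pe$df1, pe$df2)
  }
  p_values <- vapply(obs$mass, function(m) (1 + sum(null_max >= m)) / (1 + n_perm), 0)
  obs$p_value <- p_values
  structure(
    list(
      clusters = obs, effect = effect, threshold = thr,
      threshold_p = threshold_p, n_perm = n_perm,
      df1 = pe$df1, df2 = pe$df2, null_max = null_max,
      f_obs = as_map(f_obs), scheme = scheme
    ),
    class = "cluster_result"
  )
}

# 0-based row permutations, one column per (permutation, subject) draw
# (subject fastest), restricted to the exchangeability blocks
draw_permutations <- function(n_c, n_draws, blocks) {
  out <- matrix(seq_len(n_c) - 1L, n_c, n_draws)
  for (blk in blocks) {
    nb <- length(blk)
    if (nb < 2L) next
    idx <- order(rep(seq_len(n_draws), each = nb), stats::runif(nb * n_draws))
    rel <- idx - rep((seq_len(n_draws) - 1L) * nb, each = nb)
    out[blk, ] <- matrix(blk[rel], nb, n_draws) - 1L
  }
  out
}

# condition-index blocks within which labels are exchangeable
permutation_blocks <- function(design, factors, effect, scheme) {
  if (scheme == "full") {
    return(list(seq_len(nrow(design))))
  }
  in_eff <- strsplit(effect, ":", fixed = TRUE)[[1]]
  others <- setdiff(factors, in_eff)
  if (length(others) == 0L) {
    return(list(seq_len(nrow(design))))
  }
  key <- do.call(paste, design[others])
  unname(split(seq_len(nrow(design)), key))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result: effect %s, F(%d, %d) threshold %.2f (p < %g), %d permutations>\n",
    x$effect, x$df1, x$df2, x$threshold, x$threshold_p, x$n_perm
  ))
  if (nrow(x$clusters) == 0L) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(dplyr::select(x$clusters, -"members"))
  }
  invisible(x)
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$clusters, -"members"),
    effect = x$effect, .before = 1
  )
}

#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    effect = x$effect,
    n_clusters = nrow(x$clusters),
    min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_,
    threshold = x$threshold,
    n_perm = x$n_perm
  )
}

#' @rdname autoplot-pitchonset
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, times = NULL, alpha = 0.05, ...) {
  f <- object$f_obs
  if (is.matrix(f)) f <- apply(f, 2, max)
  tt <- if (is.null(times)) seq_along(f) else times
  df <- tibble::tibble(time = tt, F = f)
  sig <- dplyr::filter(object$clusters, .data$p_value <= alpha)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(
      x = if (is.null(times)) "sample" else "time (ms)", y = "F",
      title = sprintf("%s (cluster p < %g shaded)", object$effect, alpha)
    )
  if (nrow(sig) > 0 && !is.matrix(object$f_obs)) {
    shade <- purrr::map_dfr(sig$members, function(m) {
      tibble::tibble(xmin = tt[min(m)], xmax = tt[max(m)])
    })
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE
    )
  }
  p
}

#' Export a cluster report as JSON and flat CSV
#'
#' Writes the observed clusters of a [cluster_permutation_test()] result
#' (effect, sample windows, mass, permutation p) to a JSON report and/or a
#' flat CSV table.
#'
#' @param x A `cluster_result`.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @param times_ms Optional time axis; when given, cluster extents are also
#'   reported in ms.
#' @return A tibble with one row per cluster, invisibly.
#' @export
write_cluster_report <- function(x, json_path = NULL, csv_path = NULL,
                                 times_ms = NULL) {
  stopifnot(inherits(x, "cluster_result"))
  tab <- dplyr::mutate(
    tidy.cluster_result(x),
    start = vapply(x$clusters$members, min, 0L),
    end = vapply(x$clusters$members, max, 0L)
  )
  if (!is.null(times_ms)) {
    tab$start_ms <- times_ms[tab$start]
    tab$end_ms <- times_ms[tab$end]
  }
  if (!is.null(json_path)) {
    report <- list(
      effect = x$effect, threshold = x$threshold,
      threshold_p = x$threshold_p, n_perm = x$n_perm,
      df = c(x$df1, x$df2),
      clusters = tab[setdiff(names(tab), "effect")]
    )
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) readr::write_csv(tab, csv_path)
  invisible(tab)
}
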