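#' Vertex count of a subdivided icosahedron (closed form)
#'
#' A surface mesh obtained by recursively subdividing each triangle of an
#' icosahedron into four has `10 * 4^s + 2` vertices after `s` subdivisions
#' (ico-5, the usual cortical source-space subsampling, has 10,242).
#'
#' @param subdivisions Non-negative integer `s`.
#' @return Vertex count.
#' @examples
#' icosphere_vertex_count(0) # 12
#' icosphere_vertex_count(5) # 10242
#' @export
icosphere_vertex_count <- function(subdivisions) {
  if (subdivisions < 0 || subdivisions != round(subdivisions)) {
    stop("`subdivisions` must be a non-negative integer.", call. = FALSE)
  }
  10 * 4^subdivisions + 2
}

#' Toy cortical-surface mesh: recursively subdivided icosahedron
#'
#' Constructs the icosphere explicitly: starting from the 12-vertex
#' icosahedron, each subdivision splits every triangle into four by edge
#' midpoints (deduplicated across neighboring triangles). The result stands
#' in for a cortical surface when testing spatiotemporal cluster statistics:
#' only the adjacency (edge) structure is used downstream. Every vertex has
#' degree 6 except the 12 original icosahedron vertices, which keep degree 5.
#'
#' @param subdivisions Integer in `[0, 5]`.
#' @return A list of class `mesh_graph` with `n_vertices`, `edges` (a
#'   two-column matrix of 1-based vertex pairs, each undirected edge once),
#'   and `vertices` (n x 3 unit-sphere coordinates).
#' @examples
#' m <- make_toy_mesh(1)
#' m$n_vertices # 42
#' nrow(m$edges) # 120
#' @export
make_toy_mesh <- function(subdivisions) {
  if (subdivisions < 0 || subdivisions > 5 || subdivisions != round(subdivisions)) {
    stop("`subdivisions` must be an integer in [0, 5].", call. = FALSE)
  }
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    # midpoint index for every face edge, deduplicated via a keyed lookup
    e_all <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
    uk <- unique(key)
    mid_of <- match(key, uk) + nrow(v)
    first <- match(uk, key)
    mids <- (v[e_all[first, 1], , drop = FALSE] + v[e_all[first, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    a <- mid_of[seq_len(nf)]
    b <- mid_of[nf + seq_len(nf)]
    c_ <- mid_of[2 * nf + seq_len(nf)]
    f <- rbind(
      cbind(f[, 1], a, c_),
      cbind(f[, 2], b, a),
      cbind(f[, 3], c_, b),
      cbind(a, b, c_)
    )
  }
  e_all <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- unique(cbind(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2])))
  structure(
    list(n_vertices = nrow(v), edges = unname(e), vertices = unname(v)),
    class = "mesh_graph"
  )
}

#' @export
print.mesh_graph <- function(x, ...) {
  cat(sprintf("<mesh_graph: %d vertices, %d edges>\n", x$n_vertices, nrow(x$edges)))
  invisible(x)
}

#' Vertex degrees of a mesh graph
#' @param mesh A [make_toy_mesh()] result.
#' @return Integer vector of vertex degrees.
#' @export
mesh_degrees <- function(mesh) {
  tabulate(c(mesh$edges[, 1], mesh$edges[, 2]), nbins = mesh$n_vertices)
}

#' Write a mesh adjacency as an edge-list CSV
#' @param mesh A `mesh_graph`.
#' @param path CSV path (columns `from`, `to`).
#' @return `path`, invisibly.
#' @export
write_mesh_edges <- function(mesh, path) {
  readr::write_csv(tibble::tibble(from = mesh$edges[, 1], to = mesh$edges[, 2]), path)
  invisible(path)
}
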