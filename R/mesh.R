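#' Triangle surface mesh
#'
#' Constructs a triangle mesh from a numeric `V x 3` vertex matrix (mm) and an
#' integer `F x 3` face matrix of 1-based vertex indices. Faces are stored
#' counter-clockwise so that the right-hand rule gives the outward normal.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param validate check mesh invariants (finite coordinates, index range,
#'   no degenerate faces).
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices` and `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns (triangles only)")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate triangle mesh invariants
#'
#' Checks finite coordinates, face indices within `[1, V]`, absence of
#' degenerate faces (repeated indices within a triangle) and, optionally,
#' that the mesh is edge-connected.
#'
#' @param mesh a `triangle_mesh`.
#' @param require_connected error if the mesh has more than one
#'   edge-connected component (templates must be single-component).
#' @return The mesh, invisibly.
#' @export
validate_mesh <- function(mesh, require_connected = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh vertices contain non-finite coordinates")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) {
      bad <- which(f < 1L | f > nrow(v), arr.ind = TRUE)[1L, ]
      stop(sprintf("face %d references vertex index %d outside [1, %d]",
                   bad[1L], f[bad[1L], bad[2L]], nrow(v)))
    }
    degen <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
    if (any(degen)) {
      stop(sprintf("degenerate face(s) with repeated vertex indices: %s",
                   paste(utils::head(which(degen), 5L), collapse = ", ")))
    }
  }
  if (require_connected && n_mesh_components(mesh) != 1L) {
    stop("mesh is not a single edge-connected component")
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return Integer matrix with two columns, each row an undirected edge
#'   (smaller index first), without duplicates.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[!duplicated(e), , drop = FALSE]
}

# igraph handle on the vertex-edge graph (used for components and geodesics)
mesh_graph <- function(mesh, weighted = FALSE) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  if (weighted) {
    w <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                       mesh$vertices[e[, 2L], , drop = FALSE])^2))
    igraph::E(g)$weight <- w
  }
  g
}

n_mesh_components <- function(mesh) {
  igraph::components(mesh_graph(mesh))$no
}

#' Is every edge shared by exactly two faces?
#'
#' @param mesh a `triangle_mesh`.
#' @return Logical; `TRUE` for a closed (watertight) surface.
#' @export
is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' Enclosed volume of a closed oriented mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin); positive for outward-oriented closed surfaces.
#'
#' @param mesh a `triangle_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Euler characteristic V - E + F
#'
#' @param mesh a `triangle_mesh`.
#' @return Integer Euler characteristic (2 for a closed genus-0 surface).
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}
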