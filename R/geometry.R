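row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

#' Face normals and areas
#'
#' @param mesh a `triangle_mesh`.
#' @return List with `normals` (F x 3 unit outward normals, CCW convention)
#'   and `areas` (length-F triangle areas, mm^2).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- row_cross(e1, e2)
  len <- row_norms(cr)
  if (any(len == 0)) stop("zero-area face(s): ",
                          paste(utils::head(which(len == 0), 5L), collapse = ", "))
  list(normals = cr / len, areas = len / 2)
}

#' Angle-weighted outward vertex normals
#'
#' Each incident face's unit normal is weighted by the interior angle of the
#' triangle at the vertex, a choice robust to irregular triangulations.
#'
#' @param mesh a `triangle_mesh` with counter-clockwise (outward) faces.
#' @return `V x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(mesh)$normals
  nrm <- matrix(0, nrow(v), 3L)
  for (j in 1:3) {
    a <- f[, j]
    b <- f[, (j %% 3L) + 1L]
    c_ <- f[, ((j + 1L) %% 3L) + 1L]
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c_, , drop = FALSE] - v[a, , drop = FALSE]
    cs <- rowSums(u * w) / (row_norms(u) * row_norms(w))
    ang <- acos(pmin(1, pmax(-1, cs)))
    s <- rowsum(fn * ang, group = a)
    idx <- as.integer(rownames(s))
    nrm[idx, ] <- nrm[idx, ] + s
  }
  len <- row_norms(nrm)
  if (any(len == 0)) {
    stop("zero-area one-ring at vertex/vertices: ",
         paste(utils::head(which(len == 0), 5L), collapse = ", "))
  }
  nrm / len
}

#' Barycentric vertex areas
#'
#' One third of the area of each incident triangle is attributed to each of
#' its corners, so vertex areas sum exactly to the total surface area.
#'
#' @param mesh a `triangle_mesh`.
#' @return Numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  fa <- face_normals(mesh)$areas
  va <- numeric(nrow(mesh$vertices))
  for (j in 1:3) {
    s <- rowsum(fa / 3, group = mesh$faces[, j])
    idx <- as.integer(rownames(s))
    va[idx] <- va[idx] + as.numeric(s)
  }
  va
}
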