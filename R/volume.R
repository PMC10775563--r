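#' Binary segmentation volume
#'
#' A 3D logical array with isotropic or anisotropic voxel spacing (mm) and a
#' world-space origin. Voxel `[i, j, k]` is centred at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param voxels 3D logical (or coercible) array.
#' @param spacing length-3 positive voxel spacing in mm (scalar recycled).
#' @param origin length-3 world offset in mm of voxel `[1, 1, 1]`.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("binary_volume: %s voxels, spacing (%g, %g, %g) mm, %d foreground\n",
              paste(dim(x$voxels), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$voxels)))
  invisible(x)
}

#' Dice overlap coefficient of two binary volumes
#'
#' `2|A n B| / (|A| + |B|)`. The two volumes must share grid dimensions,
#' spacing and origin. Undefined (error) when both masks are empty.
#'
#' @param a,b `binary_volume` objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "binary_volume"), inherits(b, "binary_volume"))
  if (!identical(dim(a$voxels), dim(b$voxels)) ||
      any(abs(a$spacing - b$spacing) > 1e-9) ||
      any(abs(a$origin - b$origin) > 1e-9)) {
    stop("volumes are not on the same grid")
  }
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0L) stop("Dice undefined: both masks empty")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Read a binary volume from NIfTI-1
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param threshold voxels strictly above this value are foreground.
#' @return A `binary_volume` with spacing from `pixdim` and origin from the
#'   stored affine translation.
#' @export
read_volume <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  binary_volume(array(as.array(img) > threshold, dim = dim(img)[1:3]),
                spacing = spacing, origin = origin)
}

#' Write a binary volume to NIfTI-1
#'
#' @param vol a `binary_volume`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- array(as.integer(vol$voxels), dim = dim(vol$voxels))
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- isosurface extraction ----

# Kuhn 6-tetrahedra decomposition of the unit cube around diagonal c0-c6.
# Corner order: (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)
.tet_decomp <- rbind(c(0, 5, 1, 6), c(0, 1, 2, 6), c(0, 2, 3, 6),
                     c(0, 3, 7, 6), c(0, 7, 4, 6), c(0, 4, 5, 6)) + 1L

# triangles per inside-mask (bit i = tet vertex i inside), as local edge pairs
.tet_cases <- local({
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  edge_between <- function(a, b) {
    for (i in seq_along(pairs)) {
      if (setequal(pairs[[i]], c(a, b))) return(i)
    }
  }
  cases <- vector("list", 16L)
  for (mask in 1:14) {
    inside <- which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) != 0L)
    outside <- setdiff(1:4, inside)
    tri <- NULL
    if (length(inside) == 1L) {
      i <- inside
      e <- vapply(outside, function(o) edge_between(i, o), 0L)
      tri <- matrix(e, 1L, 3L)
    } else if (length(inside) == 3L) {
      o <- outside
      e <- vapply(inside, function(i) edge_between(i, o), 0L)
      tri <- matrix(e, 1L, 3L)
    } else if (length(inside) == 2L) {
      i1 <- inside[1L]; i2 <- inside[2L]
      o1 <- outside[1L]; o2 <- outside[2L]
      a <- edge_between(i1, o1); b <- edge_between(i1, o2)
      c_ <- edge_between(i2, o2); d <- edge_between(i2, o1)
      tri <- rbind(c(a, b, c_), c(a, c_, d))
    }
    cases[[mask + 1L]] <- tri
  }
  cases
})

#' Extract a triangle mesh from a binary volume
#'
#' Builds the 0.5 isosurface of a binary volume by tetrahedral decomposition
#' of each grid cell (the marching-tetrahedra variant of marching cubes,
#' which has no ambiguous cases), with crossings placed at edge midpoints.
#' The volume is zero-padded so the result is always closed. The mesh is
#' then consistently oriented outward, and optionally smoothed by iterating
#' the umbrella (uniform Laplacian) operator
#' `v <- v + lambda * (mean(neighbours) - v)`, which preserves the vertex
#' count and topology.
#'
#' @param volume a `binary_volume` with non-empty foreground.
#' @param laplacian_iters number of smoothing iterations (0 = raw surface).
#' @param laplacian_lambda smoothing step in `(0, 1]`.
#' @return A closed, outward-oriented `triangle_mesh` in world coordinates.
#' @export
marching_cubes_mesh <- function(volume, laplacian_iters = 10L,
                                laplacian_lambda = 0.5) {
  stopifnot(inherits(volume, "binary_volume"))
  vox <- volume$voxels
  if (!any(vox)) stop("empty foreground: nothing to mesh")
  d <- dim(vox)
  # pad one sample layer of background on every side
  pd <- d + 2L
  pad <- array(FALSE, pd)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vox
  nx <- pd[1L]; ny <- pd[2L]; nz <- pd[3L]
  lin <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  corner_ids <- sapply(1:8, function(c8) {
    lin(ci + corner_off[c8, 1L], cj + corner_off[c8, 2L],
        ck + corner_off[c8, 3L])
  })
  inside <- matrix(pad[corner_ids], nrow = length(ci))
  keep <- rowSums(inside) > 0L & rowSums(inside) < 8L
  corner_ids <- corner_ids[keep, , drop = FALSE]
  inside <- inside[keep, , drop = FALSE]
  tri_e1 <- integer(0); tri_e2 <- integer(0); tri_e3 <- integer(0)
  pairs_tab <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (t in seq_len(nrow(.tet_decomp))) {
    tc <- .tet_decomp[t, ]
    tid <- corner_ids[, tc, drop = FALSE]       # cells x 4 global ids
    tin <- inside[, tc, drop = FALSE]
    mask <- tin[, 1L] + 2L * tin[, 2L] + 4L * tin[, 3L] + 8L * tin[, 4L]
    for (m in 1:14) {
      rows <- which(mask == m)
      if (!length(rows)) next
      tris <- .tet_cases[[m + 1L]]
      for (r in seq_len(nrow(tris))) {
        for (col in 1:3) {
          pr <- pairs_tab[tris[r, col], ]
          g1 <- tid[rows, pr[1L]]
          g2 <- tid[rows, pr[2L]]
          eid <- pmin(g1, g2) * (nx * ny * nz + 1) + pmax(g1, g2)
          if (col == 1L) e1 <- eid else if (col == 2L) e2 <- eid else e3 <- eid
        }
        tri_e1 <- c(tri_e1, e1); tri_e2 <- c(tri_e2, e2)
        tri_e3 <- c(tri_e3, e3)
      }
    }
  }
  all_e <- c(tri_e1, tri_e2, tri_e3)
  uniq <- sort(unique(all_e))
  f <- cbind(match(tri_e1, uniq), match(tri_e2, uniq), match(tri_e3, uniq))
  big <- nx * ny * nz + 1
  gmin <- floor(uniq / big)
  gmax <- uniq - gmin * big
  to_xyz <- function(g) {
    g0 <- g - 1
    k <- g0 %/% (nx * ny)
    j <- (g0 - k * nx * ny) %/% nx
    i <- g0 - k * nx * ny - j * nx
    cbind(i, j, k)  # 0-based padded grid indices
  }
  mid <- (to_xyz(gmin) + to_xyz(gmax)) / 2
  # padded index 1 corresponds to original index 0, i.e. world origin - spacing
  verts <- sweep(sweep(mid - 1, 2L, volume$spacing, `*`), 2L,
                 volume$origin, `+`)
  f <- orient_faces(f, verts)
  mesh <- triangle_mesh(verts, f)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  if (laplacian_iters > 0L) {
    mesh <- laplacian_smooth(mesh, laplacian_iters, laplacian_lambda)
  }
  mesh
}

# breadth-first consistent orientation of a manifold triangle soup
orient_faces <- function(f, verts) {
  nf <- nrow(f)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e_all <- rbind(cbind(f[, 1L], f[, 2L]), cbind(f[, 2L], f[, 3L]),
                 cbind(f[, 3L], f[, 1L]))
  keys <- ekey(e_all[, 1L], e_all[, 2L])
  face_of <- rep(seq_len(nf), 3L)
  adj <- split(face_of, keys)
  visited <- logical(nf)
  flipped <- logical(nf)
  for (start in seq_len(nf)) {
    if (visited[start]) next
    visited[start] <- TRUE
    queue <- start
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      fc <- if (flipped[cur]) f[cur, c(1L, 3L, 2L)] else f[cur, ]
      dir_edges <- rbind(fc[c(1L, 2L)], fc[c(2L, 3L)], fc[c(3L, 1L)])
      for (r in 1:3) {
        key <- ekey(dir_edges[r, 1L], dir_edges[r, 2L])
        for (nb in adj[[key]]) {
          if (nb == cur || visited[nb]) next
          nbf <- f[nb, ]
          nb_dir <- rbind(nbf[c(1L, 2L)], nbf[c(2L, 3L)], nbf[c(3L, 1L)])
          same <- any(nb_dir[, 1L] == dir_edges[r, 1L] &
                      nb_dir[, 2L] == dir_edges[r, 2L])
          # neighbour must traverse the shared edge in the opposite direction
          flipped[nb] <- same
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  f[flipped, ] <- f[flipped, c(1L, 3L, 2L), drop = FALSE]
  f
}

#' Uniform Laplacian (umbrella) mesh smoothing
#'
#' @param mesh a `triangle_mesh`.
#' @param iterations number of smoothing passes.
#' @param lambda step size in `(0, 1]`.
#' @return Smoothed `triangle_mesh` with identical topology.
#' @export
laplacian_smooth <- function(mesh, iterations = 10L, lambda = 0.5) {
  e <- mesh_edges(mesh)
  v <- mesh$vertices
  nv <- nrow(v)
  deg <- tabulate(c(e[, 1L], e[, 2L]), nv)
  for (it in seq_len(iterations)) {
    acc <- matrix(0, nv, 3L)
    s1 <- rowsum(v[e[, 2L], , drop = FALSE], group = e[, 1L])
    acc[as.integer(rownames(s1)), ] <- acc[as.integer(rownames(s1)), ] + s1
    s2 <- rowsum(v[e[, 1L], , drop = FALSE], group = e[, 2L])
    acc[as.integer(rownames(s2)), ] <- acc[as.integer(rownames(s2)), ] + s2
    nbmean <- acc / pmax(deg, 1L)
    v <- v + lambda * (nbmean - v)
  }
  mesh$vertices <- v
  mesh
}

#' Voxelize a closed mesh
#'
#' Marks as foreground every voxel whose centre lies inside the mesh, using
#' ray-parity counting along the z axis. The grid defaults to the mesh
#' bounding box padded by one voxel.
#'
#' @param mesh a closed, oriented `triangle_mesh`.
#' @param spacing voxel spacing in mm (scalar or length 3). Default 2 mm,
#'   close to the source MRI resolution class.
#' @param origin optional world coordinate of voxel `[1, 1, 1]`.
#' @param dims optional grid dimensions.
#' @return A `binary_volume`; warns if no voxel centre falls inside.
#' @export
voxelize <- function(mesh, spacing = 2, origin = NULL, dims = NULL) {
  if (!is_closed_mesh(mesh)) stop("mesh is not closed; voxelization undefined")
  spacing <- rep_len(as.numeric(spacing), 3L)
  v <- mesh$vertices
  bbmin <- apply(v, 2L, min)
  bbmax <- apply(v, 2L, max)
  if (is.null(origin)) origin <- bbmin - spacing
  if (is.null(dims)) dims <- pmax(2L, as.integer(ceiling((bbmax - origin) / spacing)) + 2L)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  # tiny deterministic ray offset avoids rays through triangle edges
  epsx <- 1.37e-7 * spacing[1L]
  epsy <- 2.71e-7 * spacing[2L]
  xs <- origin[1L] + (seq_len(nx) - 1L) * spacing[1L] + epsx
  ys <- origin[2L] + (seq_len(ny) - 1L) * spacing[2L] + epsy
  zs <- origin[3L] + (seq_len(nz) - 1L) * spacing[3L]
  f <- mesh$faces
  cross_col <- vector("list", nx * ny)
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  for (tr in seq_len(nrow(f))) {
    p1 <- a[tr, ]; p2 <- b[tr, ]; p3 <- c_[tr, ]
    det2 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
            (p3[1] - p1[1]) * (p2[2] - p1[2])
    if (abs(det2) < 1e-14) next   # triangle vertical w.r.t. z rays
    xi <- which(xs >= min(p1[1], p2[1], p3[1]) & xs <= max(p1[1], p2[1], p3[1]))
    yi <- which(ys >= min(p1[2], p2[2], p3[2]) & ys <= max(p1[2], p2[2], p3[2]))
    if (!length(xi) || !length(yi)) next
    gx <- rep(xs[xi], times = length(yi))
    gy <- rep(ys[yi], each = length(xi))
    l1 <- ((p2[1] - gx) * (p3[2] - gy) - (p3[1] - gx) * (p2[2] - gy)) / det2
    l2 <- ((p3[1] - gx) * (p1[2] - gy) - (p1[1] - gx) * (p3[2] - gy)) / det2
    l3 <- 1 - l1 - l2
    hit <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(hit)) next
    zhit <- l1[hit] * p1[3] + l2[hit] * p2[3] + l3[hit] * p3[3]
    cols <- (rep(xi, times = length(yi)) +
             (rep(yi, each = length(xi)) - 1L) * nx)[hit]
    for (q in seq_along(cols)) {
      cross_col[[cols[q]]] <- c(cross_col[[cols[q]]], zhit[q])
    }
  }
  vox <- array(FALSE, dims)
  for (col in which(lengths(cross_col) > 0L)) {
    zc <- sort(cross_col[[col]])
    if (length(zc) %% 2L != 0L) next   # grazing contact; skip degenerate column
    ix <- ((col - 1L) %% nx) + 1L
    iy <- ((col - 1L) %/% nx) + 1L
    for (p in seq(1L, length(zc), by = 2L)) {
      inside <- zs > zc[p] & zs < zc[p + 1L]
      vox[ix, iy, inside] <- TRUE
    }
  }
  if (!any(vox)) warning("no voxel centre fell inside the mesh")
  binary_volume(vox, spacing = spacing, origin = origin)
}
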