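# Small meshes and cohorts built in code for the tests.

# regular tetrahedron (closed, outward-oriented)
tetrahedron_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  m <- triangle_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# regular icosahedron with unit-ish vertices
icosahedron_mesh <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(1 + p^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- triangle_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# refined icosphere: subdivide each face, project to unit sphere
icosphere_mesh <- function(levels = 2) {
  m <- icosahedron_mesh()
  for (l in seq_len(levels)) {
    v <- m$vertices
    f <- m$faces
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    newv <- list()
    midpoint <- function(a, b) {
      k <- ekey(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      newv[[length(newv) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      id <- nrow(v) + length(newv)
      mids[[k]] <- id
      id
    }
    nf <- list()
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[[length(nf) + 1L]] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                     c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    v <- v / sqrt(rowSums(v^2))
    m <- triangle_mesh(v, do.call(rbind, nf))
  }
  m
}

# flat triangulated square patch in z = 0, CCW seen from +z
flat_patch_mesh <- function(n = 4) {
  g <- expand.grid(x = 0:n, y = 0:n)
  v <- cbind(g$x, g$y, 0)
  id <- function(i, j) i + 1L + j * (n + 1L)
  f <- list()
  for (i in 0:(n - 1)) {
    for (j in 0:(n - 1)) {
      f[[length(f) + 1L]] <- rbind(c(id(i, j), id(i + 1, j), id(i, j + 1)),
                                   c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
    }
  }
  triangle_mesh(v, do.call(rbind, f))
}

# vertices-only "mesh" for explicit-edge TFCE tests (e.g. a path graph)
bare_vertex_mesh <- function(V) {
  triangle_mesh(cbind(seq_len(V), 0, 0), matrix(integer(0), 0, 3))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, byrow = TRUE)
}

apply_rigid <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(R), 2L, t, `+`)
  mesh
}

# deterministic scan for a covariate draw that represents the nominal
# study conditions and keeps the full model estimable: each disease flag
# has >= min_count positives (interaction terms need several cases), its
# count lies inside the central 95% binomial band of its configured
# prevalence (so a single-replicate test is not run on a tail draw), and
# the ethnicity indicator varies
estimable_covariates <- function(n, seed, spec, min_count = 4L) {
  in_band <- function(count, p) {
    count >= stats::qbinom(0.025, n, p) && count <= stats::qbinom(0.975, n, p)
  }
  s <- seed
  repeat {
    covs <- sample_covariates(n, seed = s, spec = spec)
    if (sum(covs$T2D) >= min_count && sum(covs$liver_disease) >= min_count &&
        in_band(sum(covs$T2D), spec$prevalence$T2D) &&
        in_band(sum(covs$liver_disease), spec$prevalence$liver_disease) &&
        length(unique(covs$ethnicity)) > 1L) {
      return(list(covs = covs, seed = s))
    }
    s <- s + 1L
  }
}

# machinery-test cohort spec: boosted prevalences so that disease terms are
# estimable at small N (the generator's epidemiological defaults are
# exercised separately)
test_spec <- function(n_subjects, v_target, sigma = 1, effects = NULL,
                      seed = 1L) {
  cohort_spec(n_subjects = n_subjects, v_target = v_target,
              prevalence = list(liver_disease = 0.15, T2D = 0.25),
              noise = list(sigma = sigma, corr_length = 15),
              effects = effects, seed = seed)
}

write_tetra_ply <- function(path) {
  m <- tetrahedron_mesh()
  write_mesh(m, path)
  m
}
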