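test_that("mesh construction enforces invariants", {
  m <- tetrahedron_mesh()
  expect_s3_class(m, "triangle_mesh")
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)
  expect_error(triangle_mesh(m$vertices, rbind(m$faces, c(1, 2, 10))),
               "outside")
  expect_error(triangle_mesh(m$vertices, rbind(m$faces, c(1, 1, 2))),
               "degenerate")
  bad <- m$vertices
  bad[1, 1] <- NaN
  expect_error(triangle_mesh(bad, m$faces), "non-finite")
})

test_that("mesh I/O round-trips exactly and rejects malformed files", {
  m <- make_template_mesh(300, seed = 11)
  for (ext in c("ply", "off", "vtk")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, p)
    m2 <- read_mesh(p)
    expect_identical(m2$vertices, m$vertices, label = ext)
    expect_identical(m2$faces, m$faces, label = ext)
  }
  # per-vertex fields survive PLY and VTK
  fld <- list(s2s = sin(seq_len(nrow(m$vertices))))
  for (ext in c("ply", "vtk")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, p, fields = fld)
    got <- attr(read_mesh(p), "fields")$s2s
    expect_equal(got, fld$s2s, tolerance = 1e-15)
  }
  # out-of-range face index named in the error
  p <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 5",
               "property double x", "property double y", "property double z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1", "1 1 1",
               "3 0 1 9"), p)
  expect_error(read_mesh(p), "outside")
  # quad faces are refused, not triangulated
  p2 <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), p2)
  expect_error(read_mesh(p2), "triangles")
})

test_that("binary little-endian PLY files are read", {
  m <- tetrahedron_mesh()
  p <- withr::local_tempfile(fileext = ".ply")
  con <- file(p, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4",
               "property list uchar int vertex_indices", "end_header"), con)
  writeBin(as.numeric(t(m$vertices)), con, size = 4, endian = "little")
  for (i in seq_len(4)) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4, endian = "little")
  }
  close(con)
  m2 <- read_mesh(p)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-7)
  expect_identical(m2$faces, m$faces)
})

test_that("vertex normals match analytic directions", {
  # unit sphere: normal is the position vector
  sph <- icosphere_mesh(3)   # 1280 faces at level 3
  expect_gte(nrow(sph$faces), 1280)
  n <- vertex_normals(sph)
  ang <- acos(pmin(1, rowSums(n * sph$vertices)))
  expect_lt(max(ang) * 180 / pi, 5)
  # flat CCW patch: all (0, 0, 1)
  fp <- flat_patch_mesh(4)
  nf <- vertex_normals(fp)
  expect_equal(nf, matrix(rep(c(0, 0, 1), each = nrow(fp$vertices)),
                          ncol = 3), tolerance = 1e-12)
  # icosahedron: normal parallel to vertex direction by symmetry
  ico <- icosahedron_mesh()
  ni <- vertex_normals(ico)
  dir <- ico$vertices / sqrt(rowSums(ico$vertices^2))
  expect_equal(abs(rowSums(ni * dir)), rep(1, 12), tolerance = 1e-9)
})

test_that("vertex areas conserve total surface area", {
  # two unit right triangles sharing an edge -> total area 1
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                     rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_equal(sum(vertex_areas(m)), 1.0, tolerance = 1e-12)
  # uniform icosahedron: all vertex areas equal
  ico <- icosahedron_mesh()
  va <- vertex_areas(ico)
  expect_equal(va, rep(va[1], 12), tolerance = 1e-12)
  # exact conservation on generated meshes (property over several seeds)
  for (s in 1:3) {
    tm <- make_template_mesh(400, seed = s)
    expect_equal(sum(vertex_areas(tm)), sum(face_normals(tm)$areas),
                 tolerance = 1e-12)
  }
  # high-resolution unit sphere: total ~ 4*pi within 1%
  sph <- icosphere_mesh(4)
  expect_equal(sum(vertex_areas(sph)), 4 * pi, tolerance = 0.01)
})

test_that("rigid alignment recovers exact transforms", {
  m <- make_template_mesh(300, seed = 5)
  moved <- apply_rigid(m, rotation_z(pi / 6), c(5, 0, 0))
  al <- rigid_align(moved, m)
  expect_lt(al$residual_rms, 1e-9)
  expect_equal(al$rotation %*% rotation_z(pi / 6), diag(3), tolerance = 1e-9)
  # identity on self
  al2 <- rigid_align(m, m)
  expect_equal(al2$transform, diag(4), tolerance = 1e-9)
  # scale recovery
  sc <- m
  sc$vertices <- sc$vertices * 1.2
  al3 <- rigid_align(sc, m, allow_scaling = TRUE)
  expect_equal(al3$scale, 1 / 1.2, tolerance = 1e-9)
  expect_lt(al3$residual_rms, 1e-9)
  expect_error(rigid_align(tetrahedron_mesh(), m), "mismatch")
})

test_that("s2s distance has the outward-positive sign convention", {
  m <- make_template_mesh(300, seed = 6)
  expect_equal(s2s_distance(m, m), rep(0, nrow(m$vertices)))
  n <- vertex_normals(m)
  inflate <- m
  inflate$vertices <- m$vertices + 2 * n
  expect_equal(s2s_distance(m, inflate), rep(2, nrow(m$vertices)),
               tolerance = 1e-6)
  shrink <- m
  shrink$vertices <- m$vertices - 1.5 * n
  expect_equal(s2s_distance(m, shrink), rep(-1.5, nrow(m$vertices)),
               tolerance = 1e-6)
  bad <- inflate
  bad$vertices[3, 2] <- Inf
  expect_error(s2s_distance(m, bad), "non-finite")
})

test_that("s2s is equivariant under simultaneous rigid motion", {
  m <- make_template_mesh(300, seed = 7)
  n <- vertex_normals(m)
  subj <- m
  set.seed(1)
  subj$vertices <- m$vertices + stats::rnorm(nrow(m$vertices)) * n
  d0 <- s2s_distance(m, subj)
  R <- rotation_z(0.7)
  d1 <- s2s_distance(apply_rigid(m, R, c(3, -2, 1)),
                     apply_rigid(subj, R, c(3, -2, 1)))
  expect_lt(max(abs(d1 - d0)), 1e-6)
})

test_that("generalized Procrustes mean reproduces shapes", {
  m <- make_template_mesh(300, seed = 8)
  copies <- list(m, apply_rigid(m, rotation_z(0.4), c(1, 2, 3)),
                 apply_rigid(m, rotation_z(-0.9), c(-4, 0, 2)))
  mean_mesh <- mean_shape_template(copies)
  expect_lt(rigid_align(mean_mesh, m)$residual_rms, 1e-6)
  # identical inputs converge in one iteration
  same <- mean_shape_template(list(m, m))
  expect_equal(attr(same, "iterations"), 1L)
  expect_equal(same$vertices, m$vertices, tolerance = 1e-12)
  # symmetric +/- bump cancels in the mean
  n <- vertex_normals(m)
  bump <- exp(-rowSums(sweep(m$vertices, 2, m$vertices[1, ])^2) / 400)
  up <- m; up$vertices <- m$vertices + 3 * bump * n
  dn <- m; dn$vertices <- m$vertices - 3 * bump * n
  mm <- mean_shape_template(list(up, dn))
  expect_lt(rigid_align(mm, m)$residual_rms, 0.05)
  expect_error(mean_shape_template(list(m)), "at least two")
  expect_error(mean_shape_template(list(m, tetrahedron_mesh())),
               "not corresponded")
})

test_that("template distance summaries follow order statistics", {
  m <- make_template_mesh(300, seed = 9)
  s0 <- template_distance_summary(m, m)
  expect_equal(unname(s0), c(0, 0))
  n <- vertex_normals(m)
  b <- m
  b$vertices <- m$vertices + 1 * n
  s1 <- template_distance_summary(m, b)
  expect_equal(unname(s1["median"]), 1, tolerance = 0.05)
  # +2 mm on exactly half the vertices -> median 1
  V <- nrow(m$vertices)
  half <- rep(c(2, 0), length.out = V)
  c_ <- m
  c_$vertices <- m$vertices + half * n
  # skip rigid realignment effects by summarising the raw field
  d <- s2s_distance(m, c_)
  expect_equal(median(d), 1, tolerance = 1e-9)
})
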