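#' Rigid (Procrustes) alignment of corresponded meshes
#'
#' Least-squares rotation + translation (optionally isotropic scale) mapping
#' `moving` onto `fixed`, assuming vertex correspondence by index. The
#' closed-form Kabsch/Umeyama solution is used; reflections are excluded.
#'
#' @param moving,fixed corresponded `triangle_mesh` objects (equal vertex
#'   count, same face topology).
#' @param allow_scaling also estimate an isotropic scale factor. Subjects are
#'   aligned rigidly (no scaling) before S2S computation; the scaling flag
#'   exists for template experiments.
#' @return List with `mesh` (transformed copy of `moving`), `transform`
#'   (4 x 4 homogeneous matrix, including scale), `rotation`, `translation`,
#'   `scale` and `residual_rms` (mm).
#' @export
rigid_align <- function(moving, fixed, allow_scaling = FALSE) {
  P <- moving$vertices
  Q <- fixed$vertices
  if (nrow(P) != nrow(Q)) stop("vertex count mismatch between moving and fixed")
  if (!identical(dim(moving$faces), dim(fixed$faces))) {
    stop("face topology mismatch between moving and fixed")
  }
  pbar <- colMeans(P)
  qbar <- colMeans(Q)
  Pc <- sweep(P, 2L, pbar)
  Qc <- sweep(Q, 2L, qbar)
  H <- crossprod(Pc, Qc)                 # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)            # R %*% p ~ q
  s <- if (allow_scaling) {
    sum(sv$d * c(1, 1, d)) / sum(Pc * Pc)
  } else 1
  t_vec <- qbar - s * as.numeric(R %*% pbar)
  aligned <- s * Pc %*% t(R)
  aligned <- sweep(aligned, 2L, qbar, `+`)
  resid <- sqrt(mean(rowSums((aligned - Q)^2)))
  tf <- diag(4)
  tf[1:3, 1:3] <- s * R
  tf[1:3, 4] <- t_vec
  out <- moving
  out$vertices <- aligned
  list(mesh = out, transform = tf, rotation = R, translation = t_vec,
       scale = s, residual_rms = resid)
}

#' Signed surface-to-surface (S2S) distance
#'
#' Per-vertex signed displacement of a corresponded subject mesh relative to
#' a template: magnitude is the Euclidean distance between corresponding
#' vertices; the sign is that of the projection of the displacement onto the
#' template's outward vertex normal, so positive values mean outward
#' expansion of the subject and negative values inward shrinkage. The
#' subject must already be rigidly aligned to the template.
#'
#' @param template,subject corresponded `triangle_mesh` objects.
#' @param normals optional precomputed template vertex normals (`V x 3`).
#' @return Numeric length-V vector of signed distances (mm).
#' @export
s2s_distance <- function(template, subject, normals = NULL) {
  if (nrow(template$vertices) != nrow(subject$vertices)) {
    stop("vertex count mismatch between template and subject")
  }
  if (!all(is.finite(subject$vertices)) || !all(is.finite(template$vertices))) {
    stop("non-finite vertex coordinates")
  }
  if (is.null(normals)) normals <- vertex_normals(template)
  disp <- subject$vertices - template$vertices
  mag <- row_norms(disp)
  sgn <- sign(rowSums(disp * normals))
  mag * ifelse(sgn == 0 & mag > 0, 1, sgn)   # pure tangential moves count positive
}

#' Generalized Procrustes mean shape
#'
#' Iteratively aligns all corresponded meshes rigidly to the current mean
#' and averages vertex positions, until the mean moves less than `tol`
#' (RMS, mm) or `max_iter` is reached. Deterministic given input order.
#'
#' @param meshes list of at least two corresponded `triangle_mesh` objects.
#' @param tol convergence tolerance on the RMS motion of the mean (mm).
#' @param max_iter iteration cap.
#' @param allow_scaling estimate isotropic scale during alignment.
#' @return A `triangle_mesh` mean shape; attribute `iterations` records the
#'   number of iterations run.
#' @export
mean_shape_template <- function(meshes, tol = 1e-4, max_iter = 50L,
                                allow_scaling = FALSE) {
  if (length(meshes) < 2L) stop("need at least two meshes")
  V <- nrow(meshes[[1L]]$vertices)
  for (m in meshes) {
    if (nrow(m$vertices) != V ||
        !identical(dim(m$faces), dim(meshes[[1L]]$faces))) {
      stop("meshes are not corresponded (vertex/face mismatch)")
    }
  }
  mean_mesh <- meshes[[1L]]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    acc <- matrix(0, V, 3L)
    for (m in meshes) {
      acc <- acc + rigid_align(m, mean_mesh, allow_scaling)$mesh$vertices
    }
    new_v <- acc / length(meshes)
    move <- sqrt(mean(rowSums((new_v - mean_mesh$vertices)^2)))
    mean_mesh$vertices <- new_v
    if (move < tol || iter >= max_iter) break
  }
  attr(mean_mesh, "iterations") <- iter
  mean_mesh
}

#' Median and IQR of inter-template S2S distance
#'
#' Rigidly aligns template B to template A and summarises the signed
#' per-vertex S2S distance between them.
#'
#' @param template_a,template_b corresponded `triangle_mesh` templates.
#' @return Named numeric vector `c(median =, iqr =)` in mm.
#' @export
template_distance_summary <- function(template_a, template_b) {
  aligned <- rigid_align(template_b, template_a)$mesh
  d <- s2s_distance(template_a, aligned)
  c(median = stats::median(d), iqr = stats::IQR(d))
}
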