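#' TFCE and permutation parameters
#'
#' Canonical TFCE exponents are `E = 0.5`, `H = 2`; thresholds are
#' `n_steps` equal steps of `max(|t|) / n_steps`. Cluster extent can be the
#' suprathreshold vertex count or (default) the summed barycentric vertex
#' areas, which is invariant to mesh resolution.
#'
#' @param E extent exponent (> 0).
#' @param H height exponent (> 0).
#' @param n_steps number of threshold steps (>= 10).
#' @param extent_mode `"area"` or `"vertex"`.
#' @param n_perm number of permutations (a warning is issued below 100,
#'   where the p-value granularity becomes coarse).
#' @param seed master seed for the permutation streams.
#' @param alpha FDR significance level in (0, 1).
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, n_steps = 100L,
                        extent_mode = c("area", "vertex"),
                        n_perm = 1000L, seed = 1L, alpha = 0.05) {
  extent_mode <- match.arg(extent_mode)
  if (E <= 0 || H <= 0) stop("E and H must be positive")
  if (n_steps < 10L) stop("n_steps must be at least 10")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_perm < 100L) {
    warning("n_perm < 100 gives coarse permutation p-values")
  }
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 extent_mode = extent_mode, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), alpha = alpha),
            class = "tfce_params")
}

#' Vertex-wise ordinary least squares across a cohort
#'
#' Fits the same linear model at every vertex, sharing one pseudoinverse:
#' `beta = (X'X)^-1 X' Y`, with t-statistics from the per-vertex residual
#' variance on `N - P` degrees of freedom. Vertices with (numerically) zero
#' residual variance get a standard-error floor of 1e-12 and a warning.
#'
#' @param cohort a `corresponded_cohort` (or bare `N x V` matrix).
#' @param design a `design_matrix`.
#' @return List of class `mur_fit` with `beta` (P x V), `t` (P x V), `se`,
#'   `df`, and the design.
#' @export
fit_mur <- function(cohort, design) {
  Y <- if (inherits(cohort, "corresponded_cohort")) cohort$s2s else as.matrix(cohort)
  X <- design$X
  N <- nrow(X)
  P <- ncol(X)
  if (nrow(Y) != N) stop("cohort rows do not match design rows")
  if (N <= P) stop("need N > P")
  XtX_inv <- solve(crossprod(X))
  pinv <- XtX_inv %*% t(X)
  beta <- pinv %*% Y
  resid <- Y - X %*% beta
  df <- N - P
  sigma2 <- colSums(resid^2) / df
  cjj <- diag(XtX_inv)
  se <- sqrt(outer(cjj, sigma2))
  if (any(se < 1e-12)) {
    warning("zero residual variance at some vertices; applying SE floor 1e-12")
    se <- pmax(se, 1e-12)
  }
  tmat <- beta / se
  dimnames(beta) <- dimnames(tmat) <- list(colnames(X), NULL)
  structure(list(beta = beta, t = tmat, se = se, df = df, design = design,
                 XtX_inv = XtX_inv, pinv = pinv),
            class = "mur_fit")
}

#' Threshold-free cluster enhancement on a mesh
#'
#' Signed TFCE: the positive part of the statistic map is enhanced by
#' `TFCE(v) = sum_h e(v,h)^E h^H dh` over `n_steps` equal threshold steps up
#' to `max(t)`, where `e(v,h)` is the extent (vertex count or summed vertex
#' areas) of the edge-connected component of `{u : t(u) >= h}` containing
#' `v`; the negative part is enhanced identically on `-t` and subtracted,
#' so the output sign matches the statistic's sign.
#'
#' @param t_map finite numeric length-V statistic map.
#' @param mesh the host `triangle_mesh`.
#' @param params a `tfce_params`.
#' @param edges,weights optional precomputed `mesh_edges(mesh)` and extent
#'   weights, to avoid recomputation in permutation loops.
#' @return Numeric length-V enhanced map.
#' @export
tfce_enhance <- function(t_map, mesh, params = tfce_params(),
                         edges = NULL, weights = NULL) {
  if (!all(is.finite(t_map))) stop("t_map contains non-finite values")
  if (length(t_map) != nrow(mesh$vertices)) stop("t_map length != V")
  if (is.null(edges)) edges <- mesh_edges(mesh)
  if (is.null(weights)) {
    weights <- if (params$extent_mode == "area") {
      vertex_areas(mesh)
    } else rep(1, nrow(mesh$vertices))
  }
  .tfce_cpp(as.numeric(t_map), edges[, 1L] - 1L, edges[, 2L] - 1L,
            as.numeric(weights), params$E, params$H, params$n_steps)
}

#' Permutation inference with TFCE and FDR control
#'
#' For every covariate of interest, runs Freedman-Lane permutation: the
#' reduced (nuisance-only) model is fitted, its residual rows are permuted
#' with a seeded stream, pseudo-data are reconstituted, and the full-model
#' t-map and its TFCE enhancement are recomputed per permutation. Two-sided
#' vertex p-values are
#' `p(v) = (1 + #{perm : |TFCE_perm(v)| >= |TFCE_obs(v)|}) / (1 + n_perm)`
#' (the observed map is included, so p is never 0), then adjusted across
#' vertices by Benjamini-Hochberg separately per covariate. Per-covariate
#' permutation streams are derived deterministically from `params$seed`.
#'
#' @param cohort a `corresponded_cohort`.
#' @param design a `design_matrix`.
#' @param params a `tfce_params`.
#' @param covariates covariate names to test; default `design$of_interest`.
#' @param verbose print per-covariate progress.
#' @return A `mur_result`: per covariate a list with `beta` (native units),
#'   `beta_std` (per-SD units when a standardization record exists), `t`,
#'   `tfce`, `p`, `q`, `sig` (q < alpha); plus `fit`, `params`, `mesh`.
#' @export
permutation_inference <- function(cohort, design, params = tfce_params(),
                                  covariates = NULL, verbose = FALSE) {
  X <- design$X
  N <- nrow(X)
  P <- ncol(X)
  if (is.null(covariates)) covariates <- design$of_interest
  if (!all(covariates %in% colnames(X))) {
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, colnames(X)), collapse = ", "))
  }
  mesh <- cohort$template
  Y <- cohort$s2s
  edges <- mesh_edges(mesh)
  weights <- if (params$extent_mode == "area") {
    vertex_areas(mesh)
  } else rep(1, nrow(mesh$vertices))

  fit <- fit_mur(cohort, design)
  Qfull <- qr.Q(qr(X))
  cjj <- diag(fit$XtX_inv)
  df <- fit$df
  col_ss <- function(M) colSums(M^2)

  results <- list()
  for (nm in covariates) {
    j <- match(nm, colnames(X))
    t_obs <- fit$t[j, ]
    tfce_obs <- tfce_enhance(t_obs, mesh, params, edges, weights)
    # reduced (nuisance-only) model
    Z <- X[, -j, drop = FALSE]
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) stop("reduced model rank deficient for ", nm)
    Qz <- qr.Q(qz)
    fitted_z <- Qz %*% crossprod(Qz, Y)
    resid_z <- Y - fitted_z
    pinv_j <- fit$pinv[j, ]
    count_ge <- numeric(ncol(Y))
    perm_seed <- derive_seed(params$seed, paste0("perm:", nm))
    with_seed(perm_seed, {
      for (b in seq_len(params$n_perm)) {
        idx <- sample.int(N)
        Ystar <- fitted_z + resid_z[idx, , drop = FALSE]
        beta_j <- as.numeric(pinv_j %*% Ystar)
        rss <- col_ss(Ystar) - col_ss(crossprod(Qfull, Ystar))
        se_j <- pmax(sqrt(pmax(rss, 0) / df * cjj[j]), 1e-12)
        t_star <- beta_j / se_j
        tfce_star <- tfce_enhance(t_star, mesh, params, edges, weights)
        count_ge <- count_ge + (abs(tfce_star) >= abs(tfce_obs))
      }
    })
    p <- (1 + count_ge) / (1 + params$n_perm)
    q <- stats::p.adjust(p, method = "BH")
    sig <- q < params$alpha
    sdrec <- design$standardization
    scl <- sdrec$scale[match(nm, sdrec$column)]
    beta_native <- fit$beta[j, ]
    beta_std <- NULL
    if (isTRUE(sdrec$standardized[1L])) {
      beta_std <- beta_native            # standardized design: already per SD
      if (!is.na(scl)) beta_native <- beta_native / scl
    } else if (!is.na(scl)) {
      beta_std <- fit$beta[j, ] * scl    # native design: rescale to per-SD
    }
    results[[nm]] <- list(beta = beta_native, beta_std = beta_std,
                          t = t_obs, tfce = tfce_obs, p = p, q = q, sig = sig)
    if (verbose) {
      message(sprintf("%s: %.1f%% of vertices significant at q < %g", nm,
                      100 * mean(sig), params$alpha))
    }
  }
  structure(list(covariates = results, fit = fit, params = params,
                 mesh = mesh, design = design),
            class = "mur_result")
}

#' @export
print.mur_result <- function(x, ...) {
  cat(sprintf("mur_result: %d covariates, %d vertices, %d permutations\n",
              length(x$covariates), length(x$covariates[[1L]]$p),
              x$params$n_perm))
  for (nm in names(x$covariates)) {
    cat(sprintf("  %-24s sig area %6.2f%%\n", nm,
                100 * mean(x$covariates[[nm]]$sig)))
  }
  invisible(x)
}

#' Significance areas and sign-split coefficient summaries
#'
#' For each tested covariate: the percentage of mesh vertices significant at
#' `q < alpha`, split into negative- and positive-coefficient areas, with
#' the median and IQR of the coefficient over each significant sign subset
#' (reported as `NA` and printed as "ns" when a subset is empty).
#'
#' @param result a `mur_result`.
#' @return A `data.frame` with one row per covariate: `covariate`,
#'   `total_pct`, `neg_pct`, `pos_pct`, `beta_neg_median`, `beta_neg_iqr`,
#'   `beta_pos_median`, `beta_pos_iqr`.
#' @export
significance_area <- function(result) {
  rows <- lapply(names(result$covariates), function(nm) {
    r <- result$covariates[[nm]]
    neg <- r$sig & r$beta < 0
    pos <- r$sig & r$beta > 0
    data.frame(
      covariate = nm,
      total_pct = 100 * mean(r$sig),
      neg_pct = 100 * mean(neg),
      pos_pct = 100 * mean(pos),
      beta_neg_median = if (any(neg)) stats::median(r$beta[neg]) else NA_real_,
      beta_neg_iqr = if (any(neg)) stats::IQR(r$beta[neg]) else NA_real_,
      beta_pos_median = if (any(pos)) stats::median(r$beta[pos]) else NA_real_,
      beta_pos_iqr = if (any(pos)) stats::IQR(r$beta[pos]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an area-summary table as CSV
#'
#' Formats coefficients as `median (IQR)` with "ns" for empty subsets,
#' mirroring the usual presentation of sign-split significance areas.
#'
#' @param area output of [significance_area()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_area_summary <- function(area, path) {
  fmt <- function(m, iqr) ifelse(is.na(m), "ns", sprintf("%.2f (%.2f)", m, iqr))
  out <- data.frame(
    covariate = area$covariate,
    beta_negative = fmt(area$beta_neg_median, area$beta_neg_iqr),
    area_negative_pct = sprintf("%.2f", area$neg_pct),
    beta_positive = fmt(area$beta_pos_median, area$beta_pos_iqr),
    area_positive_pct = sprintf("%.2f", area$pos_pct),
    area_total_pct = sprintf("%.2f", area$total_pct))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-vertex statistic maps as VTK PolyData
#'
#' @param result a `mur_result`.
#' @param dir output directory (created if needed); one
#'   `<covariate>.vtk` per tested covariate with arrays beta, t, tfce, p,
#'   q, sig (and beta_std when available).
#' @return The directory, invisibly.
#' @export
write_mur_maps <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$covariates)) {
    r <- result$covariates[[nm]]
    fields <- list(beta = r$beta, t = r$t, tfce = r$tfce, p = r$p, q = r$q,
                   sig = as.numeric(r$sig))
    if (!is.null(r$beta_std)) fields$beta_std <- r$beta_std
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9_]+", "_", nm), ".vtk"))
    write_mesh(result$mesh, fn, fields = fields, format = "vtk")
  }
  invisible(dir)
}
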