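# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic per-stage substream of a master seed, kept below 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435.0)
  as.integer((seed * 48271 + h) %% 2147480009)
}

#' Cohort specification for the synthetic generator
#'
#' Bundles every parameter that determines a synthetic corresponded-mesh
#' cohort: sample size, template resolution, covariate marginals, disease
#' prevalences, ground-truth effect amplitudes and the noise model. The
#' same spec and seed always regenerate an identical cohort.
#'
#' Default disease prevalences are 0.013 for liver disease and 0.053 for
#' type-2 diabetes (449/33,434 and 1,780/33,434). Default effect amplitudes
#' follow the reported per-unit shape effects: age -0.11 mm/yr (broad),
#' BMI +0.30 mm/unit (broad), PDFF +0.26 mm/% (broad), T2D +2.4 mm
#' (regional), liver disease -2.1 mm in one region and +1.95 mm in another,
#' PDFF-by-T2D +0.10 mm/%, age-by-T2D -0.03 mm/yr. Noise is spatially
#' correlated Gaussian with 2 mm marginal SD and 15 mm correlation length.
#'
#' @param n_subjects cohort size.
#' @param v_target target template vertex count.
#' @param prevalence named list, probabilities of `liver_disease` and `T2D`.
#' @param noise list with `sigma` (mm) and `corr_length` (mm); set
#'   `sigma = 0` for a noiseless cohort.
#' @param effects list of effect definitions (see [make_effect_maps()]);
#'   `NULL` uses the defaults above.
#' @param seed master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 300L, v_target = 2000L,
                        prevalence = list(liver_disease = 0.013, T2D = 0.053),
                        noise = list(sigma = 2, corr_length = 15),
                        effects = NULL, seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be at least 2")
  if (v_target < 100L) stop("v_target must be at least 100")
  stopifnot(is.list(prevalence), is.list(noise))
  if (is.null(effects)) effects <- default_effects()
  structure(list(n_subjects = as.integer(n_subjects),
                 v_target = as.integer(v_target),
                 prevalence = prevalence, noise = noise,
                 effects = effects, seed = as.integer(seed)),
            class = "cohort_spec")
}

default_effects <- function() {
  list(
    list(covariate = "age", amplitude = -0.11, extent = "broad"),
    list(covariate = "BMI", amplitude = 0.30, extent = "broad"),
    list(covariate = "liver_PDFF", amplitude = 0.26, extent = "broad"),
    list(covariate = "T2D", amplitude = 2.4, extent = "regional"),
    list(covariate = "liver_disease", amplitude = -2.1, extent = "regional"),
    list(covariate = "liver_disease", amplitude = 1.95, extent = "regional"),
    list(covariate = "liver_PDFF:T2D", amplitude = 0.10, extent = "broad"),
    list(covariate = "age:T2D", amplitude = -0.03, extent = "broad")
  )
}

#' Synthetic liver-like template mesh
#'
#' Deterministically builds a closed, asymmetric genus-0 surface: a UV-sphere
#' triangulation (vertex count within 10% of `v_target`) radially mapped
#' onto a superellipsoid with liver-scale semi-axes (85, 60, 45 mm) and
#' 2-3 smooth lobe protrusions whose position and size depend on the seed.
#'
#' @param v_target target vertex count (>= 100).
#' @param seed RNG seed; same seed gives a bit-identical mesh.
#' @return A closed `triangle_mesh`.
#' @export
make_template_mesh <- function(v_target = 2000L, seed = 1L) {
  if (v_target < 100L) stop("v_target must be at least 100")
  n_lat <- max(3L, round(sqrt((v_target - 2) / 2)))
  n_lon <- max(3L, round((v_target - 2) / n_lat))
  sph <- uv_sphere(n_lat, n_lon)
  dirs <- sph$vertices
  with_seed(derive_seed(seed, "template"), {
    ax <- c(85, 60, 45)
    p <- 2.5
    r_base <- (abs(dirs[, 1] / ax[1])^p + abs(dirs[, 2] / ax[2])^p +
               abs(dirs[, 3] / ax[3])^p)^(-1 / p)
    n_lobes <- sample(2:3, 1L)
    mult <- rep(1, nrow(dirs))
    for (l in seq_len(n_lobes)) {
      cdir <- stats::rnorm(3)
      cdir <- cdir / sqrt(sum(cdir^2))
      amp <- stats::runif(1L, 0.15, 0.3)
      width <- stats::runif(1L, 0.4, 0.7)
      ang <- acos(pmin(1, pmax(-1, dirs %*% cdir)))
      mult <- mult * (1 + amp * exp(-(ang / width)^2))
    }
    sph$vertices <- dirs * (r_base * mult)
  })
  sph
}

# closed UV-sphere triangulation with unit-vector vertices
uv_sphere <- function(n_lat, n_lon) {
  thetas <- pi * seq_len(n_lat) / (n_lat + 1L)
  phis <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
  grid <- expand.grid(phi = phis, theta = thetas)
  ring <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi),
                cos(grid$theta))
  v <- rbind(c(0, 0, 1), ring, c(0, 0, -1))
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  faces <- list()
  # top fan (north pole = vertex 1); CCW seen from outside
  for (j in seq_len(n_lon)) {
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  }
  for (i in seq_len(n_lat - 1L)) {
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c_ <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, c_, d)
      faces[[length(faces) + 1L]] <- c(a, d, b)
    }
  }
  south <- nrow(v)
  for (j in seq_len(n_lon)) {
    faces[[length(faces) + 1L]] <- c(south, idx(n_lat, j + 1L), idx(n_lat, j))
  }
  m <- triangle_mesh(v, do.call(rbind, faces))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' Sample a synthetic covariate table
#'
#' Draws anthropometric and liver-phenotype covariates from marginals chosen
#' to mimic a middle-aged population imaging cohort: age 44-82 yr, ~49%
#' male, ~98% European ancestry indicator, BMI around 27 kg/m2 correlated
#' with WHR, log-normal liver fat (PDFF, elevated under T2D), liver iron
#' around 1.3 mg/g, AST/ALT/platelets from which AST:ALT and FIB-4 are
#' derived (giving FIB-4 its positive age correlation), liver volume with
#' BMI and age trends, and configurable disease prevalences.
#'
#' @param n number of subjects (>= 2).
#' @param seed RNG seed.
#' @param spec a `cohort_spec` (prevalences are read from it).
#' @return A `data.frame` with one row per subject.
#' @export
sample_covariates <- function(n, seed = 1L, spec = cohort_spec()) {
  if (n < 2L) stop("n must be at least 2")
  stopifnot(inherits(spec, "cohort_spec"))
  p_ld <- spec$prevalence$liver_disease
  p_t2d <- spec$prevalence$T2D
  if (is.null(p_ld) || is.null(p_t2d) || p_ld < 0 || p_ld > 1 ||
      p_t2d < 0 || p_t2d > 1) {
    stop("invalid prevalence specification")
  }
  with_seed(derive_seed(seed, "covariates"), {
    age <- pmin(82, pmax(44, stats::rnorm(n, 63, 7.5)))
    sex <- stats::rbinom(n, 1L, 0.487)
    ethnicity <- stats::rbinom(n, 1L, 0.976)
    BMI <- pmax(16.5, stats::rnorm(n, 27, 4.3))
    WHR <- pmax(0.6, 0.55 + 0.011 * BMI + 0.06 * sex + stats::rnorm(n, 0, 0.05))
    T2D <- stats::rbinom(n, 1L, p_t2d)
    liver_disease <- stats::rbinom(n, 1L, p_ld)
    liver_PDFF <- pmin(40, exp(stats::rnorm(n, log(3.5), 0.6)) + 4 * T2D)
    liver_iron <- pmax(0.5, stats::rnorm(n, 1.3, 0.25))
    AST <- exp(stats::rnorm(n, log(26), 0.25))
    ALT <- exp(stats::rnorm(n, log(23), 0.35))
    platelets <- pmax(100, stats::rnorm(n, 250, 55))
    liver_volume <- pmax(500, 1200 + 25 * (BMI - 27) - 5 * (age - 60) +
                           stats::rnorm(n, 0, 180))
    scan_hour <- sample(8:20, n, replace = TRUE)
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, ethnicity = ethnicity, BMI = BMI, WHR = WHR,
      liver_PDFF = liver_PDFF, liver_iron = liver_iron,
      AST = AST, ALT = ALT, platelets = platelets,
      AST_ALT = derive_ast_alt(AST, ALT),
      FIB4 = derive_fib4(age, AST, ALT, platelets),
      liver_volume = liver_volume,
      liver_disease = liver_disease, T2D = T2D,
      scan_hour = scan_hour,
      stringsAsFactors = FALSE
    )
  })
}

#' Ground-truth per-vertex effect maps
#'
#' Builds one smooth per-vertex effect map (mm per covariate unit) for each
#' entry of `spec$effects`. Each map is a geodesic-radial bump: flat at the
#' stated amplitude within half the radius, cosine-tapered to exactly zero
#' at the radius (so the recorded support equals the set of vertices with
#' non-zero effect). Geodesic distance is the graph shortest path over mesh
#' edges. Broad effects default to a 140 mm radius, regional ones to 55 mm;
#' centres are drawn per seed. Interaction effects are named
#' `"a:b"` (e.g. `"age:T2D"`).
#'
#' @param template a `triangle_mesh`.
#' @param spec a `cohort_spec`.
#' @param seed RNG seed for bump centres.
#' @return An `effect_map_set`: list with `maps` (named list of length-V
#'   vectors; multiple bumps for one covariate are summed), `support`
#'   (named list of logical vectors), `noise` and `bumps` (audit table).
#' @export
make_effect_maps <- function(template, spec = cohort_spec(), seed = 1L) {
  V <- nrow(template$vertices)
  g <- mesh_graph(template, weighted = TRUE)
  mean_edge <- mean(igraph::E(g)$weight)
  max_geo <- max(igraph::distances(g, v = 1L))
  maps <- list()
  support <- list()
  bumps <- list()
  with_seed(derive_seed(seed, "effects"), {
    for (eff in spec$effects) {
      radius <- if (!is.null(eff$radius)) eff$radius else {
        if (identical(eff$extent, "broad")) 140 else 55
      }
      if (radius > 2 * max_geo) {
        stop(sprintf("bump radius %.0f mm exceeds mesh extent (%.0f mm)",
                     radius, max_geo))
      }
      center <- if (!is.null(eff$center)) eff$center else sample.int(V, 1L)
      d <- as.numeric(igraph::distances(g, v = center))
      k <- tukey_bump(d, radius)
      map <- eff$amplitude * k
      nm <- eff$covariate
      if (is.null(maps[[nm]])) {
        maps[[nm]] <- map
      } else {
        maps[[nm]] <- maps[[nm]] + map
      }
      support[[nm]] <- abs(maps[[nm]]) > 0
      bumps[[length(bumps) + 1L]] <- data.frame(
        covariate = nm, amplitude = eff$amplitude, center = center,
        radius = radius)
    }
  })
  structure(list(maps = maps, support = support, noise = spec$noise,
                 bumps = do.call(rbind, bumps), mean_edge = mean_edge),
            class = "effect_map_set")
}

# flat within r/2, cosine taper to 0 at r
tukey_bump <- function(d, radius) {
  k <- numeric(length(d))
  k[d <= radius / 2] <- 1
  tz <- d > radius / 2 & d < radius
  k[tz] <- 0.5 * (1 + cos(pi * (d[tz] - radius / 2) / (radius / 2)))
  k
}

# spatially correlated Gaussian field on the mesh graph:
# white noise smoothed by umbrella iterations, rescaled to unit variance
smooth_noise_field <- function(n, edges, V, sigma, corr_length, mean_edge) {
  z <- matrix(stats::rnorm(n * V), n, V)
  if (sigma == 0) return(matrix(0, n, V))
  iters <- max(1L, round((corr_length / mean_edge)^2 / 2))
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), V)
  lambda <- 0.6
  for (it in seq_len(iters)) {
    acc <- matrix(0, n, V)
    g1 <- rowsum(t(z[, edges[, 2L], drop = FALSE]), group = edges[, 1L])
    acc[, as.integer(rownames(g1))] <- t(g1)
    g2 <- rowsum(t(z[, edges[, 1L], drop = FALSE]), group = edges[, 2L])
    acc[, as.integer(rownames(g2))] <- acc[, as.integer(rownames(g2))] + t(g2)
    nb <- sweep(acc, 2L, pmax(deg, 1L), `/`)
    z <- (1 - lambda) * z + lambda * nb
  }
  # standardise the marginal scale back to sigma after smoothing
  if (n >= 10L) {
    sdv <- sqrt(pmax(colMeans(z^2) - colMeans(z)^2, 1e-12))
    sigma * sweep(z, 2L, sdv, `/`)
  } else {
    sigma * z / sqrt(mean(z^2))
  }
}

#' Generate a synthetic corresponded cohort
#'
#' Displaces every template vertex along its outward normal by
#' `d_i(v) = sum_k beta_k(v) x_ik + sum_j gamma_j(v) w_ij + eps_i(v)`,
#' where `x` are the covariates, `w` the interaction terms (products taken
#' after centering the continuous partner, matching [build_design()]), and
#' `eps` spatially correlated Gaussian noise. Because displacement is purely
#' along template normals, the signed S2S distance recomputed from the
#' generated meshes equals `d` to numerical precision.
#'
#' @param template a `triangle_mesh`.
#' @param covs covariate table from [sample_covariates()].
#' @param effects an `effect_map_set` from [make_effect_maps()].
#' @param seed RNG seed for the noise field.
#' @return A `corresponded_cohort` (see [corresponded_cohort()]) with extra
#'   elements `truth` (the N x V displacement matrix) and `normals`.
#'   Issues a warning if any subject's displaced surface has locally
#'   inverted faces (a self-intersection proxy).
#' @export
generate_cohort <- function(template, covs, effects, seed = 1L) {
  stopifnot(inherits(effects, "effect_map_set"))
  V <- nrow(template$vertices)
  N <- nrow(covs)
  X <- effect_design_columns(covs, names(effects$maps))
  B <- do.call(cbind, effects$maps)          # V x K
  D <- X %*% t(B)                            # N x V displacement
  sigma <- effects$noise$sigma
  if (sigma > 0) {
    edges <- mesh_edges(template)
    eps <- with_seed(derive_seed(seed, "noise"), {
      smooth_noise_field(N, edges, V, sigma, effects$noise$corr_length,
                         effects$mean_edge)
    })
    D <- D + eps
  }
  normals <- vertex_normals(template)
  s2s <- matrix(0, N, V)
  flipped_total <- 0L
  fn0 <- face_normals(template)$normals
  f <- template$faces
  for (i in seq_len(N)) {
    subj <- template
    subj$vertices <- template$vertices + D[i, ] * normals
    s2s[i, ] <- s2s_distance(template, subj, normals = normals)
    e1 <- subj$vertices[f[, 2L], ] - subj$vertices[f[, 1L], ]
    e2 <- subj$vertices[f[, 3L], ] - subj$vertices[f[, 1L], ]
    flipped_total <- flipped_total + sum(rowSums(row_cross(e1, e2) * fn0) < 0)
  }
  if (flipped_total > 0L) {
    warning(sprintf("%d locally inverted faces across the cohort (possible self-intersections)",
                    flipped_total))
  }
  cohort <- corresponded_cohort(template, s2s, covs$subject_id)
  cohort$truth <- D
  cohort$normals <- normals
  cohort
}

# covariate / interaction columns in generator convention:
# main effects raw, interactions as (centered continuous) * flag
effect_design_columns <- function(covs, names_needed) {
  cols <- lapply(names_needed, function(nm) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
      a <- covs[[parts[1L]]]
      b <- covs[[parts[2L]]]
      if (is.null(a) || is.null(b)) stop("unknown covariate in ", nm)
      ac <- if (is_binary_col(a)) a else a - mean(a)
      bc <- if (is_binary_col(b)) b else b - mean(b)
      ac * bc
    } else {
      x <- covs[[nm]]
      if (is.null(x)) stop("unknown covariate ", nm)
      x
    }
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names_needed
  out
}

is_binary_col <- function(x) all(x %in% c(0, 1))

#' Corresponded cohort container
#'
#' @param template a `triangle_mesh`.
#' @param s2s `N x V` matrix of signed S2S distances (mm).
#' @param subject_ids length-N labels.
#' @return A list of class `corresponded_cohort`.
#' @export
corresponded_cohort <- function(template, s2s, subject_ids) {
  s2s <- as.matrix(s2s)
  if (ncol(s2s) != nrow(template$vertices)) {
    stop("s2s column count must equal template vertex count")
  }
  if (!all(is.finite(s2s))) stop("s2s contains non-finite values")
  if (length(subject_ids) != nrow(s2s)) stop("subject_ids length mismatch")
  structure(list(template = template, s2s = s2s,
                 subject_ids = as.character(subject_ids)),
            class = "corresponded_cohort")
}

#' @export
print.corresponded_cohort <- function(x, ...) {
  cat(sprintf("corresponded_cohort: %d subjects x %d vertices; S2S range [%.2f, %.2f] mm\n",
              nrow(x$s2s), ncol(x$s2s), min(x$s2s), max(x$s2s)))
  invisible(x)
}

#' Materialise one subject's mesh from its S2S row
#'
#' Valid for cohorts whose subjects are normal-displacements of the template
#' (the generator's regime): vertex positions are template vertices moved by
#' the signed S2S value along the template normal.
#'
#' @param cohort a `corresponded_cohort`.
#' @param i subject index.
#' @param normals optional precomputed template normals.
#' @return A `triangle_mesh`.
#' @export
cohort_subject_mesh <- function(cohort, i, normals = NULL) {
  if (is.null(normals)) {
    normals <- cohort$normals
    if (is.null(normals)) normals <- vertex_normals(cohort$template)
  }
  subj <- cohort$template
  subj$vertices <- cohort$template$vertices + cohort$s2s[i, ] * normals
  subj
}
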