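make_small_cohort <- function(N = 60, V = 400, sigma = 1, seed = 21,
                              effects = NULL) {
  tm <- make_template_mesh(V, seed = seed)
  spec <- test_spec(N, V, sigma = sigma, effects = effects, seed = seed)
  covs <- estimable_covariates(N, seed, spec)$covs
  eff <- make_effect_maps(tm, spec, seed = seed)
  cohort <- generate_cohort(tm, covs, eff, seed = seed)
  list(template = tm, covs = covs, effects = eff, cohort = cohort)
}

test_that("design matrices have the documented structure", {
  spec <- test_spec(120, 500, seed = 31)
  covs <- estimable_covariates(120, 31, spec)$covs
  d1 <- build_design(covs, model = 1)
  expect_equal(ncol(d1$X), 8L)  # intercept + 7 covariates
  expect_equal(colnames(d1$X)[1], "(Intercept)")
  d2 <- build_design(covs, model = 2, interactions = TRUE)
  expect_equal(ncol(d2$X), 8L + 4L + 4L)
  expect_true(all(c("age:T2D", "liver_PDFF:liver_disease") %in% colnames(d2$X)))
  d3 <- build_design(covs, model = 3)
  expect_equal(ncol(d3$X), 12L + length(unique(covs$scan_hour)) - 1L)
  # standardization: continuous columns z-scored, binary untouched
  ds <- build_design(covs, model = 2, standardize = TRUE)
  expect_equal(mean(ds$X[, "age"]), 0, tolerance = 1e-12)
  expect_equal(sd(ds$X[, "BMI"]), 1, tolerance = 1e-12)
  expect_true(all(ds$X[, "sex"] %in% 0:1))
  # constant flag cannot enter an interaction
  covs0 <- covs
  covs0$liver_disease <- 0
  expect_error(build_design(covs0, model = 2, interactions = TRUE),
               "constant")
  # collinearity is named
  covs2 <- covs
  covs2$WHR <- covs2$BMI
  expect_error(build_design(covs2, model = 1), "collinear")
  covs3 <- covs
  covs3$BMI[1] <- NA
  expect_error(build_design(covs3, model = 1), "missing")
})

test_that("vertex-wise OLS matches a per-vertex lm oracle", {
  dat <- make_small_cohort(N = 40, V = 120, sigma = 1, seed = 22)
  design <- build_design(dat$covs, model = 2)
  fit <- fit_mur(dat$cohort, design)
  sub <- 1:25
  orc <- lm_oracle(dat$cohort$s2s[, sub, drop = FALSE], design$X)
  expect_equal(unname(fit$beta[, sub]), orc$beta, tolerance = 1e-8)
  expect_equal(unname(fit$t[, sub]), orc$t, tolerance = 1e-8)
  # hand-computable toy: slope 2 with zero residual -> SE floor engages
  X <- cbind(1, 0:4)
  Y <- cbind(c(1, 3, 5, 7, 9), rep(0, 5))
  toy_design <- structure(list(X = X, of_interest = "slope",
                               standardization = data.frame(
                                 column = c("(Intercept)", "slope"),
                                 center = NA, scale = NA,
                                 standardized = FALSE),
                               model = 1, interactions = FALSE),
                          class = "design_matrix")
  colnames(toy_design$X) <- c("(Intercept)", "slope")
  expect_warning(toyfit <- fit_mur(Y, toy_design), "SE floor")
  expect_equal(unname(toyfit$beta["slope", 1]), 2, tolerance = 1e-12)
  expect_gt(toyfit$t["slope", 1], 1e10)
  # all-zero response column -> zero beta and t
  expect_equal(unname(toyfit$beta[, 2]), c(0, 0))
  expect_equal(unname(toyfit$t[, 2]), c(0, 0))
})

test_that("noiseless cohorts are recovered exactly", {
  dat <- make_small_cohort(N = 50, V = 200, sigma = 0, seed = 23)
  design <- build_design(dat$covs, model = 2, interactions = TRUE)
  fit <- suppressWarnings(fit_mur(dat$cohort, design))
  B <- do.call(cbind, dat$effects$maps)
  expect_lt(max(abs(t(fit$beta[colnames(B), ]) - B)), 1e-8)
})

test_that("TFCE matches the brute-force oracle on meshes and path graphs", {
  pm <- tfce_params(E = 0.5, H = 2, n_steps = 25, extent_mode = "vertex",
                    n_perm = 100)
  # spec's path-graph example
  pathV <- 6L
  mesh <- bare_vertex_mesh(pathV)
  edges <- cbind(1:5, 2:6)
  tmap <- c(0, 2, 2, 0, -2, 0)
  w <- rep(1, pathV)
  got <- tfce_enhance(tmap, mesh, pm, edges = edges, weights = w)
  want <- brute_force_tfce(tmap, edges, w, 0.5, 2, 25)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(sign(got), sign(tmap))
  # random fields on a small real mesh, vertex and area extents
  tm <- make_template_mesh(120, seed = 24)
  e <- mesh_edges(tm)
  va <- vertex_areas(tm)
  set.seed(24)
  for (rep in 1:10) {
    f <- rnorm(nrow(tm$vertices))
    for (mode in c("vertex", "area")) {
      p <- tfce_params(n_steps = 20, extent_mode = mode, n_perm = 100)
      wts <- if (mode == "area") va else rep(1, nrow(tm$vertices))
      expect_equal(tfce_enhance(f, tm, p),
                   brute_force_tfce(f, e, wts, 0.5, 2, 20),
                   tolerance = 1e-12)
    }
  }
  # zero map stays zero
  expect_equal(tfce_enhance(rep(0, nrow(tm$vertices)), tm, pm),
               rep(0, nrow(tm$vertices)))
  expect_error(tfce_enhance(c(NA, rep(0, nrow(tm$vertices) - 1)), tm, pm),
               "non-finite")
})

test_that("TFCE grows strictly with the height of a positive map", {
  tm <- make_template_mesh(150, seed = 25)
  set.seed(25)
  f <- pmax(rnorm(nrow(tm$vertices)), 0)
  pm <- tfce_params(n_steps = 50, extent_mode = "vertex", n_perm = 100)
  t1 <- tfce_enhance(f, tm, pm)
  t2 <- tfce_enhance(2 * f, tm, pm)
  supra <- t1 > 0   # vertices above the first threshold step
  expect_gt(sum(supra), 50)
  expect_true(all(t2[supra] > t1[supra]))
  expect_true(all(t2[f == 0] == 0))
})

test_that("permutation p-values are honest and rigid-invariant", {
  dat <- make_small_cohort(N = 40, V = 150, sigma = 1, seed = 26,
                           effects = list(list(covariate = "BMI",
                                               amplitude = 0.4,
                                               extent = "regional")))
  design <- build_design(dat$covs, model = 1)
  pm <- tfce_params(n_perm = 100, seed = 9, n_steps = 30)
  res <- permutation_inference(dat$cohort, design, pm, covariates = "BMI")
  p <- res$covariates$BMI$p
  expect_true(all(p >= 1 / 101 & p <= 1))
  expect_true(all(res$covariates$BMI$q >= p - 1e-12))
  expect_identical(res$covariates$BMI$sig, res$covariates$BMI$q < pm$alpha)
  # identical rerun (determinism)
  res2 <- permutation_inference(dat$cohort, design, pm, covariates = "BMI")
  expect_identical(res$covariates$BMI$p, res2$covariates$BMI$p)
  # rigid motion of every mesh leaves the inference untouched
  rot <- apply_rigid(dat$template, rotation_z(1.1), c(10, -5, 2))
  cohort_rot <- corresponded_cohort(rot, dat$cohort$s2s,
                                    dat$cohort$subject_ids)
  res3 <- permutation_inference(cohort_rot, design, pm, covariates = "BMI")
  expect_equal(res$covariates$BMI$p, res3$covariates$BMI$p)
  expect_equal(res$covariates$BMI$beta, res3$covariates$BMI$beta)
})

test_that("strong localized effects are localized by the significance mask", {
  dat <- make_small_cohort(N = 80, V = 400, sigma = 1, seed = 27,
                           effects = list(list(covariate = "BMI",
                                               amplitude = 3,
                                               extent = "regional")))
  design <- build_design(dat$covs, model = 1)
  pm <- tfce_params(n_perm = 200, seed = 11)
  res <- permutation_inference(dat$cohort, design, pm, covariates = "BMI")
  sig <- res$covariates$BMI$sig
  supp <- dat$effects$support$BMI
  core <- dat$effects$maps$BMI >= 1.5   # flat part of the bump (>= a/2)
  expect_gte(sum(sig & core) / sum(core), 0.9)
  expect_gte(2 * sum(sig & supp) / (sum(sig) + sum(supp)), 0.7)
  expect_true(all(res$covariates$BMI$beta[sig] > 0))
})

test_that("significance areas count and summarise by coefficient sign", {
  # constructed result: 25 of 100 vertices significant, 10 negative
  beta <- c(rep(-1.5, 10), rep(2, 15), rep(0.1, 75))
  fake <- structure(list(covariates = list(toy = list(
    beta = beta, q = c(rep(0.01, 25), rep(0.5, 75)),
    sig = c(rep(TRUE, 25), rep(FALSE, 75))))), class = "mur_result")
  area <- significance_area(fake)
  expect_equal(area$total_pct, 25)
  expect_equal(area$neg_pct, 10)
  expect_equal(area$pos_pct, 15)
  expect_equal(area$beta_neg_median, -1.5)
  expect_equal(area$beta_pos_median, 2)
  # nothing significant -> ns
  fake0 <- structure(list(covariates = list(toy = list(
    beta = beta, q = rep(0.9, 100), sig = rep(FALSE, 100)))),
    class = "mur_result")
  a0 <- significance_area(fake0)
  expect_equal(a0$total_pct, 0)
  expect_true(is.na(a0$beta_pos_median))
  p <- withr::local_tempfile(fileext = ".csv")
  write_area_summary(a0, p)
  expect_match(readLines(p)[2], "ns")
  # everything significant and positive
  fake1 <- structure(list(covariates = list(toy = list(
    beta = abs(beta) + 1, q = rep(0.001, 100), sig = rep(TRUE, 100)))),
    class = "mur_result")
  a1 <- significance_area(fake1)
  expect_equal(a1$total_pct, 100)
  expect_equal(a1$pos_pct, 100)
  expect_equal(a1$neg_pct, 0)
})
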