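toy_pool <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("C%03d", seq_len(n)),
             age = round(runif(n, 45, 80)),
             sex = rbinom(n, 1, 0.5),
             BMI = round(runif(n, 20, 35), 1))
}

test_that("matching respects calipers, scarcity order and no-reuse", {
  cases <- data.frame(subject_id = c("A1", "A2"), age = c(50, 60),
                      sex = c(1, 0), BMI = c(30, 25))
  # exact clones available -> matched to clones
  pool <- data.frame(subject_id = c("B1", "B2"), age = c(50, 60),
                     sex = c(1, 0), BMI = c(30, 25))
  m <- match_case_control(cases, pool)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs$control_id[m$pairs$case_id == "A1"], "B1")
  # both candidate controls violate one caliper each -> unmatched
  pool2 <- data.frame(subject_id = c("B1", "B2"), age = c(52, 50),
                      sex = c(1, 1), BMI = c(30, 33))
  m2 <- match_case_control(cases[1, ], pool2)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched, "A1")
  # one eligible control shared by two cases -> one pair, one unmatched
  cases3 <- data.frame(subject_id = c("A1", "A2"), age = c(50, 50),
                       sex = c(1, 1), BMI = c(30, 30))
  pool3 <- data.frame(subject_id = "B9", age = 50, sex = 1, BMI = 30.5)
  m3 <- match_case_control(cases3, pool3)
  expect_equal(nrow(m3$pairs), 1)
  expect_equal(length(m3$unmatched), 1)
  expect_error(match_case_control(cases, pool[0, ]), "empty")
  expect_error(match_case_control(cases, cases), "disjoint")
})

test_that("matching caliper audit holds on many random pools", {
  set.seed(7)
  for (rep in 1:40) {
    pool <- toy_pool(60, seed = rep)
    cases <- toy_pool(12, seed = rep + 1000)
    cases$subject_id <- sub("C", "A", cases$subject_id)
    m <- match_case_control(cases, pool)
    if (nrow(m$pairs)) {
      ci <- match(m$pairs$case_id, cases$subject_id)
      ki <- match(m$pairs$control_id, pool$subject_id)
      expect_true(all(abs(cases$age[ci] - pool$age[ki]) <= 1))
      expect_true(all(cases$sex[ci] == pool$sex[ki]))
      expect_true(all(abs(cases$BMI[ci] - pool$BMI[ki]) <= 2))
      expect_false(any(duplicated(m$pairs$control_id)))
    }
  }
})

test_that("SPCA reduces to PCA at zero penalty and sparsifies with l1", {
  set.seed(31)
  X <- matrix(rnorm(50 * 200), 50, 200)
  sp <- spca(X, K = 5, l1 = 0, ridge = 0)
  pc <- prcomp(X)
  for (k in 1:5) {
    expect_gte(abs(cor(sp$scores[, k], pc$x[, k])), 0.999)
  }
  expect_equal(sp$explained_variance,
               (pc$sdev^2 / sum(pc$sdev^2))[1:5], tolerance = 1e-6)
  # rank-2 toy: two components explain everything
  U <- matrix(rnorm(30 * 2), 30, 2)
  W <- matrix(rnorm(2 * 50), 2, 50)
  sp2 <- spca(U %*% W, K = 2, l1 = 0, ridge = 0)
  expect_equal(sum(sp2$explained_variance), 1, tolerance = 1e-9)
  # rank-1 + tiny noise: leading loading aligned with the true direction
  v <- rnorm(80)
  v <- v / sqrt(sum(v^2))
  X1 <- rnorm(40) %*% t(v) * 5 + matrix(rnorm(40 * 80, sd = 0.01), 40, 80)
  sp3 <- spca(X1, K = 2, l1 = 0, ridge = 0)
  expect_gte(abs(sum(sp3$loadings[, 1] * v)), 0.99)
  # sparsity strictly increases with l1 on fixed data
  spA <- spca(X, K = 5, l1 = 0, ridge = 1e-6)
  spB <- spca(X, K = 5, l1 = 20, ridge = 1e-6)
  expect_gt(mean(spB$loadings == 0), mean(spA$loadings == 0))
  # deterministic sign convention: largest-|.| entry positive
  for (k in 1:5) {
    expect_gt(spA$loadings[which.max(abs(spA$loadings[, k])), k], 0)
  }
  expect_error(spca(X[1:2, ], K = 1), "at least 3")
})

test_that("mode selection follows the cumulative variance target", {
  fake <- structure(list(explained_variance = c(0.5, 0.3, 0.15, 0.05)),
                    class = "spca_result")
  expect_equal(select_modes(fake, 0.9), 3)
  expect_equal(select_modes(fake, 0.5), 1)
  expect_equal(select_modes(fake, 1.0), 4)
  fake2 <- structure(list(explained_variance = c(0.4, 0.2)),
                     class = "spca_result")
  expect_error(select_modes(fake2, 0.9), "unreachable")
})

test_that("LOOCV prediction is protocol-correct and separable toys score 1", {
  set.seed(51)
  n_pairs <- 15
  covs <- toy_pool(2 * n_pairs, seed = 52)
  covs$ethnicity <- rbinom(2 * n_pairs, 1, 0.95)
  covs$WHR <- runif(2 * n_pairs, 0.7, 1.1)
  covs$AST_ALT <- runif(2 * n_pairs, 0.6, 2)
  covs$FIB4 <- runif(2 * n_pairs, 0.4, 3)
  covs$liver_volume <- rnorm(2 * n_pairs, 1500, 200)
  covs$liver_PDFF <- runif(2 * n_pairs, 1, 20)
  covs$liver_iron <- runif(2 * n_pairs, 0.8, 2)
  matched <- structure(list(
    pairs = data.frame(case_id = covs$subject_id[1:n_pairs],
                       control_id = covs$subject_id[(n_pairs + 1):(2 * n_pairs)],
                       d_age = 0, d_bmi = 0),
    unmatched = character(0), calipers = list(age = 1, bmi = 2)),
    class = "matched_cohort")
  # perfectly separating feature: outcome encoded in liver volume
  covs_sep <- covs
  covs_sep$liver_volume <- c(rep(2000, n_pairs), rep(1000, n_pairs))
  res <- fit_predict_loocv(matched, covs_sep, features = "volume")
  expect_equal(res$auc, 1.0)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  # each subject predicted exactly once, in cohort order
  expect_equal(length(res$probs), 2 * n_pairs)
  expect_identical(res$subject_ids,
                   c(matched$pairs$case_id, matched$pairs$control_id))
  # probabilities do not depend on subject ordering
  perm <- sample(n_pairs)
  matched_perm <- matched
  matched_perm$pairs <- matched$pairs[perm, ]
  res_perm <- fit_predict_loocv(matched_perm, covs_sep, features = "volume")
  idx <- match(res$subject_ids, res_perm$subject_ids)
  expect_equal(res_perm$probs[idx], res$probs, tolerance = 1e-6)
  # s2s model needs scores
  expect_error(fit_predict_loocv(matched, covs, features = "s2s"),
               "requires SPCA scores")
})

test_that("DeLong reduces to the Mann-Whitney identity and handles ties", {
  # 6-subject toy with a hand-countable U statistic
  labels <- c(1, 1, 1, 0, 0, 0)
  probs <- c(0.9, 0.7, 0.4, 0.8, 0.3, 0.2)
  # pairs (case > control): count = 7 of 9, one tie-free set
  expect_equal(auc_mann_whitney(probs, labels), 7 / 9)
  dl <- delong_test(probs, probs, labels)
  expect_equal(dl$auc_a, 7 / 9)
  expect_equal(dl$auc_diff, 0)
  expect_equal(dl$p_value, 1.0)
  # AUC equals the trapezoidal ROC area on tie-free data
  set.seed(61)
  y <- rep(0:1, each = 40)
  pr <- y + rnorm(80, sd = 0.8)
  expect_equal(auc_mann_whitney(pr, y), trapezoid_auc(pr, y),
               tolerance = 1e-12)
  # agreement with the reference implementation
  skip_if_not_installed("pROC")
  pr2 <- y * 0.3 + rnorm(80, sd = 0.7)
  dl2 <- delong_test(pr, pr2, y)
  ref <- pROC::roc.test(pROC::roc(y, pr, quiet = TRUE),
                        pROC::roc(y, pr2, quiet = TRUE), method = "delong")
  expect_equal(dl2$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(delong_test(pr, pr2, rep(1, 80)), "single class")
})

test_that("the AUC-versus-modes sweep returns a coherent curve", {
  set.seed(71)
  n_pairs <- 12
  covs <- toy_pool(2 * n_pairs, seed = 72)
  covs$ethnicity <- 1
  covs$WHR <- runif(2 * n_pairs, 0.7, 1.1)
  covs$AST_ALT <- runif(2 * n_pairs, 0.6, 2)
  covs$FIB4 <- runif(2 * n_pairs, 0.4, 3)
  covs$liver_volume <- rnorm(2 * n_pairs, 1500, 200)
  covs$liver_PDFF <- runif(2 * n_pairs, 1, 20)
  covs$liver_iron <- runif(2 * n_pairs, 0.8, 2)
  matched <- structure(list(
    pairs = data.frame(case_id = covs$subject_id[1:n_pairs],
                       control_id = covs$subject_id[(n_pairs + 1):(2 * n_pairs)],
                       d_age = 0, d_bmi = 0),
    unmatched = character(0), calipers = list(age = 1, bmi = 2)),
    class = "matched_cohort")
  y <- c(rep(1, n_pairs), rep(0, n_pairs))
  S <- cbind(y * 3 + rnorm(2 * n_pairs, sd = 0.5),
             matrix(rnorm(2 * n_pairs * 3), ncol = 3))
  rownames(S) <- covs$subject_id
  sp <- structure(list(scores = S,
                       explained_variance = c(0.5, 0.2, 0.2, 0.1)),
                  class = "spca_result")
  sw <- auc_vs_modes(matched, covs, sp, k_max = 3)
  expect_equal(nrow(sw$curve), 3)
  expect_equal(sw$curve$K, 1:3)
  expect_true(all(sw$curve$auc >= 0 & sw$curve$auc <= 1))
  # single-point curve
  sw1 <- auc_vs_modes(matched, covs, sp, k_max = 1)
  expect_equal(nrow(sw1$curve), 1)
  expect_error(auc_vs_modes(matched, covs, sp, k_max = 10), "exceeds")
})
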