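#' Greedy caliper case-control matching
#'
#' Matches one control to every case under hard calipers: age within
#' `calipers$age` years, identical sex, BMI within `calipers$bmi` kg/m2.
#' Cases are processed in order of scarcity (fewest eligible controls
#' first); each case takes the eligible unused control minimising |dBMI|,
#' then |dAge|, then pool order. Controls are used at most once; cases with
#' no eligible control are reported unmatched.
#'
#' @param cases,pool covariate `data.frame`s with `subject_id`, `age`,
#'   `sex`, `BMI`; ids must be disjoint.
#' @param calipers list with `age` (yr) and `bmi` (kg/m2) half-widths.
#' @return A `matched_cohort`: `pairs` (data.frame case_id, control_id,
#'   d_age, d_bmi), `unmatched` (case ids), `calipers`.
#' @export
match_case_control <- function(cases, pool,
                               calipers = list(age = 1, bmi = 2)) {
  if (nrow(pool) == 0L) stop("control pool is empty")
  if (length(intersect(cases$subject_id, pool$subject_id))) {
    stop("cases and pool are not disjoint")
  }
  nc <- nrow(cases)
  elig <- vector("list", nc)
  for (i in seq_len(nc)) {
    ok <- abs(pool$age - cases$age[i]) <= calipers$age &
      pool$sex == cases$sex[i] &
      abs(pool$BMI - cases$BMI[i]) <= calipers$bmi
    elig[[i]] <- which(ok)
  }
  order_cases <- order(lengths(elig), seq_len(nc))
  used <- logical(nrow(pool))
  pairs <- list()
  unmatched <- character(0)
  for (i in order_cases) {
    cand <- elig[[i]][!used[elig[[i]]]]
    if (!length(cand)) {
      unmatched <- c(unmatched, cases$subject_id[i])
      next
    }
    d_bmi <- abs(pool$BMI[cand] - cases$BMI[i])
    d_age <- abs(pool$age[cand] - cases$age[i])
    pick <- cand[order(d_bmi, d_age, cand)][1L]
    used[pick] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      case_id = cases$subject_id[i], control_id = pool$subject_id[pick],
      d_age = cases$age[i] - pool$age[pick],
      d_bmi = cases$BMI[i] - pool$BMI[pick],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), control_id = character(0),
               d_age = numeric(0), d_bmi = numeric(0))
  structure(list(pairs = pairs, unmatched = unmatched, calipers = calipers),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("matched_cohort: %d pairs, %d unmatched cases (age +/- %g yr, same sex, BMI +/- %g)\n",
              nrow(x$pairs), length(x$unmatched), x$calipers$age,
              x$calipers$bmi))
  invisible(x)
}

#' Sparse principal component analysis
#'
#' Alternating minimisation of
#' `0.5 ||X - X B A'||_F^2 + l1 ||B||_1 + 0.5 ridge ||B||_F^2`
#' with orthonormal `A` (variable-projection form): a proximal-gradient
#' step on the loadings `B` (soft-thresholding), then a Procrustes polar
#' update of `A`. Initialised from the SVD of `X`, so with zero penalties
#' the method reproduces standard PCA. After convergence components are
#' ordered by explained variance, loadings are rescaled to unit norm, and
#' each loading's largest-magnitude entry is made positive for sign
#' determinism.
#'
#' @param X `N x V` matrix; columns are centred internally.
#' @param K number of components.
#' @param l1 lasso penalty on loadings.
#' @param ridge ridge penalty on loadings.
#' @param max_iter,tol convergence controls on the max absolute change of
#'   `B` between iterations.
#' @return An `spca_result`: `loadings` (V x K), `scores` (N x K),
#'   `explained_variance` (fractions of total variance, via successive QR
#'   orthogonalisation of the scores), `center`, `iterations`, penalties.
#' @export
spca <- function(X, K, l1 = 1e-3, ridge = 1e-6, max_iter = 5000L,
                 tol = 1e-6) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 rows")
  K <- as.integer(K)
  if (K < 1L || K > min(dim(X))) stop("invalid number of components")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0, nv = K)
  A <- B <- sv$v[, seq_len(K), drop = FALSE]
  G <- crossprod(Xc)
  step <- 1 / (sv$d[1L]^2 + ridge)
  soft <- function(m, lam) sign(m) * pmax(abs(m) - lam, 0)
  # objective up to the constant 0.5||X||^2 (A orthonormal)
  objective <- function(A, B) {
    GB <- G %*% B
    0.5 * sum(B * GB) - sum(A * GB) + l1 * sum(abs(B)) +
      0.5 * ridge * sum(B^2)
  }
  iter <- 0L
  obj_old <- objective(A, B)
  repeat {
    iter <- iter + 1L
    B_new <- soft(B - step * (G %*% B - G %*% A + ridge * B), step * l1)
    sva <- svd(G %*% B_new)
    A <- sva$u %*% t(sva$v)
    delta <- max(abs(B_new - B))
    B <- B_new
    obj <- objective(A, B)
    rel <- abs(obj_old - obj) / max(abs(obj_old), 1e-12)
    obj_old <- obj
    if (delta < tol || rel < 1e-10) break
    if (iter >= max_iter) {
      stop(sprintf("spca did not converge in %d iterations (last delta %.3g)",
                   max_iter, delta))
    }
  }
  nrm <- sqrt(colSums(B^2))
  if (any(nrm == 0)) {
    stop("l1 penalty removed an entire component; reduce l1 or K")
  }
  B <- sweep(B, 2L, nrm, `/`)
  scores <- Xc %*% B
  # order by explained variance; adjusted for correlated sparse scores via QR
  ev_of <- function(S) {
    qrs <- qr(S)
    diag(qr.R(qrs))^2 / (nrow(S) - 1)
  }
  ord <- order(apply(scores, 2L, stats::var), decreasing = TRUE)
  B <- B[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  flip <- vapply(seq_len(K), function(k) {
    sign(B[which.max(abs(B[, k])), k])
  }, 0)
  B <- sweep(B, 2L, flip, `*`)
  scores <- sweep(scores, 2L, flip, `*`)
  total_var <- sum(apply(Xc, 2L, stats::var))
  expl <- abs(ev_of(scores)) / total_var
  structure(list(loadings = B, scores = scores,
                 explained_variance = expl, center = ctr,
                 l1 = l1, ridge = ridge, iterations = iter),
            class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  cat(sprintf("spca_result: %d modes, %.1f%% cumulative variance, %d iterations\n",
              ncol(x$loadings), 100 * sum(x$explained_variance),
              x$iterations))
  invisible(x)
}

#' Smallest number of modes reaching a cumulative variance target
#'
#' @param spca_res an `spca_result`.
#' @param target cumulative explained-variance fraction (default 0.9).
#' @return Integer number of modes.
#' @export
select_modes <- function(spca_res, target = 0.9) {
  cs <- cumsum(spca_res$explained_variance)
  k <- which(cs >= target - 1e-12)[1L]
  if (is.na(k)) {
    stop(sprintf("target %.2f unreachable: %d modes explain only %.3f",
                 target, length(cs), cs[length(cs)]))
  }
  k
}

# logistic regression with an optional tiny ridge (used when glm reports
# separation); returns coefficient vector for cbind(1, X)
logistic_ridge <- function(X, y, ridge = 1e-6, max_iter = 100L) {
  Xd <- cbind(1, X)
  beta <- numeric(ncol(Xd))
  pen <- c(0, rep(ridge, ncol(X)))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    H <- crossprod(Xd * w, Xd) + diag(pen, ncol(Xd))
    beta_new <- solve(H, crossprod(Xd * w, z))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

#' AUC by the Mann-Whitney identity
#'
#' @param probs predicted scores.
#' @param labels 0/1 outcomes.
#' @return Probability that a random case scores above a random control
#'   (ties count 1/2).
#' @export
auc_mann_whitney <- function(probs, labels) {
  x <- probs[labels == 1]
  y <- probs[labels == 0]
  if (!length(x) || !length(y)) stop("need both classes to compute AUC")
  r <- rank(c(x, y), ties.method = "average")
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}

#' Leave-one-out cross-validated disease prediction
#'
#' Fits a logistic model of the matched case-control outcome on the
#' clinical covariates (age, sex, ethnicity, BMI, WHR, AST:ALT, FIB-4,
#' liver volume, PDFF, iron) — the volume model — or on those plus the
#' first `n_modes` SPCA shape-feature scores — the S2S model. Each subject
#' is predicted by a model trained on all others; classes use a 0.5
#' probability cutoff (balanced 1:1 cohorts). If `glm` reports separation
#' the fold is refitted with a 1e-6 ridge.
#'
#' @param matched a `matched_cohort`.
#' @param covs covariate table covering all matched subjects.
#' @param scores optional `N_total x K` SPCA score matrix with rownames =
#'   subject ids (required for the S2S model).
#' @param features `"volume"` or `"s2s"`.
#' @param n_modes number of score columns to include in the S2S model.
#' @return A `prediction_result`: `auc`, `auc_ci` (DeLong 95%), `f1`,
#'   `accuracy`, `sensitivity`, `specificity`, `probs`, `labels`,
#'   `subject_ids`, `features`.
#' @export
fit_predict_loocv <- function(matched, covs, scores = NULL,
                              features = c("volume", "s2s"), n_modes = 0L) {
  features <- match.arg(features)
  ids <- c(matched$pairs$case_id, matched$pairs$control_id)
  if (!length(ids)) stop("matched cohort has no pairs")
  y <- c(rep(1, nrow(matched$pairs)), rep(0, nrow(matched$pairs)))
  idx <- match(ids, covs$subject_id)
  if (anyNA(idx)) stop("matched subject(s) missing from covariate table")
  base_cols <- c("age", "sex", "ethnicity", "BMI", "WHR", "AST_ALT", "FIB4",
                 "liver_volume", "liver_PDFF", "liver_iron")
  Xm <- as.matrix(covs[idx, base_cols])
  if (features == "s2s") {
    if (is.null(scores)) stop("s2s model requires SPCA scores")
    if (n_modes < 1L || n_modes > ncol(scores)) stop("invalid n_modes")
    sidx <- match(ids, rownames(scores))
    if (anyNA(sidx)) stop("matched subject(s) missing from score matrix")
    Xm <- cbind(Xm, scores[sidx, seq_len(n_modes), drop = FALSE])
  }
  # drop constant columns (e.g. single-ethnicity cohorts) to keep folds stable
  keep_col <- apply(Xm, 2L, function(col) stats::sd(col) > 0)
  Xm <- Xm[, keep_col, drop = FALSE]
  n <- length(y)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- Xm[-i, , drop = FALSE]
    ytr <- y[-i]
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2L, stats::sd)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(Xtr, 2L, ctr), 2L, scl, `/`)
    co <- tryCatch({
      fit <- suppressWarnings(stats::glm.fit(cbind(1, Xs), ytr,
                                             family = stats::binomial()))
      if (!fit$converged || any(abs(fit$coefficients) > 50)) {
        logistic_ridge(Xs, ytr)
      } else fit$coefficients
    }, error = function(e) logistic_ridge(Xs, ytr))
    xi <- (Xm[i, ] - ctr) / scl
    probs[i] <- 1 / (1 + exp(-(co[1L] + sum(co[-1L] * xi))))
  }
  pred <- as.integer(probs >= 0.5)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  auc <- auc_mann_whitney(probs, y)
  v <- delong_variance(probs, y)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v)))
  structure(list(
    auc = auc, auc_ci = ci,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    probs = probs, labels = y, subject_ids = ids, features = features,
    n_modes = if (features == "s2s") n_modes else 0L),
    class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s model: AUC %.2f (%.2f-%.2f), F1 %.2f, accuracy %.2f (sens/spec %.2f/%.2f)\n",
              x$features, x$auc, x$auc_ci[1L], x$auc_ci[2L], x$f1,
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

# DeLong variance of a single AUC via placement values
delong_variance <- function(probs, labels) {
  x <- probs[labels == 1]
  y <- probs[labels == 0]
  m <- length(x)
  n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  stats::var(v10) / m + stats::var(v01) / n
}

#' DeLong's test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two prediction models evaluated on the
#' same subjects, using placement-value covariances and a two-sided normal
#' reference. AUCs are computed by the Mann-Whitney identity.
#'
#' @param probs_a,probs_b per-subject scores from the two models.
#' @param labels shared 0/1 outcomes.
#' @return List with `auc_a`, `auc_b`, `auc_diff`, `se`, `z`, `p_value`.
#' @export
delong_test <- function(probs_a, probs_b, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  stopifnot(length(probs_a) == length(labels),
            length(probs_b) == length(labels))
  cases <- which(labels == 1)
  ctrls <- which(labels == 0)
  m <- length(cases)
  n <- length(ctrls)
  place <- function(probs) {
    psi <- outer(probs[cases], probs[ctrls],
                 function(a, b) (a > b) + 0.5 * (a == b))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  pa <- place(probs_a)
  pb <- place(probs_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  diff <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- if (abs(diff) < 1e-15) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  if (z == 0) p <- 1
  list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff,
       se = sqrt(max(var_diff, 0)), z = z, p_value = p)
}

#' AUC as a function of the number of SPCA modes
#'
#' Repeats [fit_predict_loocv()] for the S2S model with `K = 1..k_max`
#' modes and returns the performance curve.
#'
#' @param matched a `matched_cohort`.
#' @param covs covariate table.
#' @param spca_res an `spca_result` whose scores have subject-id rownames.
#' @param k_max largest mode count (must not exceed the computed modes).
#' @return List with `curve` (data.frame K, auc, ci_lo, ci_hi, f1,
#'   accuracy) and `best_k` (argmax AUC).
#' @export
auc_vs_modes <- function(matched, covs, spca_res, k_max) {
  if (k_max > ncol(spca_res$scores)) stop("k_max exceeds computed modes")
  rows <- lapply(seq_len(k_max), function(k) {
    r <- fit_predict_loocv(matched, covs, scores = spca_res$scores,
                           features = "s2s", n_modes = k)
    data.frame(K = k, auc = r$auc, ci_lo = r$auc_ci[1L],
               ci_hi = r$auc_ci[2L], f1 = r$f1, accuracy = r$accuracy)
  })
  curve <- do.call(rbind, rows)
  list(curve = curve, best_k = curve$K[which.max(curve$auc)])
}
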