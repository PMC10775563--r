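#' Build the mass-univariate regression design matrix
#'
#' Three nested covariate models:
#' * Model 1: age, sex, ethnicity indicator, BMI, WHR, liver PDFF,
#'   liver iron (7 covariates + intercept).
#' * Model 2: model 1 plus AST:ALT, FIB-4, liver disease, T2D; with
#'   `interactions = TRUE` also age-by-liver-disease, PDFF-by-liver-disease,
#'   age-by-T2D and PDFF-by-T2D (products formed after centering the
#'   continuous partner).
#' * Model 3: model 2 plus scan-hour-of-day indicators (reference = first
#'   observed hour).
#'
#' With `standardize = TRUE` continuous columns are z-scored (binary columns
#' and indicator dummies never are); the per-column centering/scaling record
#' is kept so coefficients can be reported in native units or per-SD.
#'
#' @param covs covariate `data.frame` (see [sample_covariates()]).
#' @param model 1, 2 or 3.
#' @param interactions add the four disease interaction terms (models 2-3).
#' @param standardize z-score continuous columns.
#' @return A `design_matrix`: list with `X` (N x P, intercept first),
#'   `of_interest` (default covariate names for inference: everything except
#'   intercept, ethnicity and scan-hour dummies), `standardization`
#'   (data.frame of centre/scale per column), `model`.
#' @export
build_design <- function(covs, model = 2L, interactions = FALSE,
                         standardize = FALSE) {
  model <- as.integer(model)
  stopifnot(model %in% 1:3)
  base1 <- c("age", "sex", "ethnicity", "BMI", "WHR", "liver_PDFF",
             "liver_iron")
  base2 <- c("AST_ALT", "FIB4", "liver_disease", "T2D")
  need <- base1
  if (model >= 2L) need <- c(need, base2)
  if (model >= 3L) need <- c(need, "scan_hour")
  missing_cols <- setdiff(need, names(covs))
  if (length(missing_cols)) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(covs[, need])) stop("covariates contain missing values; run QC first")
  if (interactions && model < 2L) {
    stop("interaction terms require model 2 or 3")
  }

  main <- setdiff(need, "scan_hour")
  constant <- main[vapply(main, function(nm) length(unique(covs[[nm]])) < 2L,
                          TRUE)]
  if (length(constant)) {
    # a constant indicator carries no information at this sample size;
    # dropping it mirrors dropping an unused factor level
    warning("dropping constant covariate column(s): ",
            paste(constant, collapse = ", "))
    main <- setdiff(main, constant)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(covs[, main, drop = FALSE]))
  binary <- vapply(main, function(nm) is_binary_col(covs[[nm]]), TRUE)
  center <- scale_ <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  for (nm in main[!binary]) {
    mu <- mean(covs[[nm]])
    sdv <- stats::sd(covs[[nm]])
    center[nm] <- mu
    scale_[nm] <- sdv
    if (standardize) {
      if (sdv == 0) stop("constant continuous column: ", nm)
      X[, nm] <- (covs[[nm]] - mu) / sdv
    }
  }

  if (interactions) {
    for (pair in list(c("age", "liver_disease"), c("liver_PDFF", "liver_disease"),
                      c("age", "T2D"), c("liver_PDFF", "T2D"))) {
      cont <- pair[1L]; flag <- pair[2L]
      if (length(unique(covs[[flag]])) < 2L) {
        stop("cannot form interaction with constant column: ", flag)
      }
      cc <- covs[[cont]] - mean(covs[[cont]])
      if (standardize) cc <- cc / stats::sd(covs[[cont]])
      nm <- paste0(cont, ":", flag)
      X <- cbind(X, cc * covs[[flag]])
      colnames(X)[ncol(X)] <- nm
      center[nm] <- NA_real_
      scale_[nm] <- if (standardize) stats::sd(covs[[cont]]) else NA_real_
    }
  }

  hour_cols <- character(0)
  if (model >= 3L) {
    hrs <- sort(unique(covs$scan_hour))
    if (length(hrs) > 1L) {
      for (h in hrs[-1L]) {
        nm <- sprintf("scan_hour_%02d", h)
        X <- cbind(X, as.numeric(covs$scan_hour == h))
        colnames(X)[ncol(X)] <- nm
        hour_cols <- c(hour_cols, nm)
      }
    }
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (nrow(X) <= ncol(X)) stop("need more subjects than design columns")

  of_interest <- setdiff(colnames(X), c("(Intercept)", "ethnicity", hour_cols))
  structure(list(X = X, of_interest = of_interest,
                 standardization = data.frame(
                   column = colnames(X),
                   center = as.numeric(center[colnames(X)]),
                   scale = as.numeric(scale_[colnames(X)]),
                   standardized = standardize,
                   row.names = NULL),
                 model = model, interactions = interactions),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: model %d, N = %d, P = %d%s\n", x$model,
              nrow(x$X), ncol(x$X),
              if (x$interactions) " (with interactions)" else ""))
  cat("  columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}
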