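#' Fibrosis-4 (FIB-4) index
#'
#' `FIB-4 = (age * AST) / (platelets * sqrt(ALT))`, with age in years, AST
#' and ALT in U/L and platelet count in 10^9/L. A marker of advanced liver
#' fibrosis.
#'
#' @param age,AST,ALT,platelets numeric vectors (recycled).
#' @return Numeric FIB-4 values.
#' @export
derive_fib4 <- function(age, AST, ALT, platelets) {
  if (any(ALT <= 0) || any(platelets <= 0) || any(AST <= 0) || any(age <= 0)) {
    stop("age, AST, ALT and platelets must all be positive")
  }
  (age * AST) / (platelets * sqrt(ALT))
}

#' AST:ALT ratio
#'
#' @param AST,ALT transaminase activities in U/L; `ALT` must be positive.
#' @return `AST / ALT`.
#' @export
derive_ast_alt <- function(AST, ALT) {
  if (any(ALT <= 0)) stop("ALT must be positive")
  AST / ALT
}

#' Discretise a scan time into hour of day
#'
#' @param x `"HH:MM"` / `"HH:MM:SS"` strings, `POSIXt` times, or numeric
#'   fractional hours.
#' @return Integer hour in 0-23 (floor).
#' @export
discretise_scan_hour <- function(x) {
  if (inherits(x, "POSIXt")) {
    return(as.integer(format(x, "%H")))
  }
  if (is.numeric(x)) {
    if (any(x < 0 | x >= 24)) stop("numeric scan time must be in [0, 24)")
    return(as.integer(floor(x)))
  }
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(:[0-9]{2})?$", x))
  hrs <- vapply(m, function(g) {
    if (length(g) == 0L) return(NA_integer_)
    h <- as.integer(g[2L])
    if (h > 23L || as.integer(g[3L]) > 59L) return(NA_integer_)
    h
  }, 0L)
  if (anyNA(hrs)) {
    stop("unparseable scan time: ",
         paste(utils::head(x[is.na(hrs)], 3L), collapse = ", "))
  }
  hrs
}

default_qc_rules <- function() {
  list(required_covariates = c("age", "sex", "ethnicity", "BMI", "WHR",
                               "liver_PDFF", "liver_iron", "AST_ALT", "FIB4",
                               "liver_volume"),
       volume_quantiles = c(0.001, 0.999),
       volume_range = NULL,          # resolved absolute range; filled by apply_qc
       auto_exclude_volume = TRUE,
       s2s_range = c(-60, 80))
}

#' Quality-control exclusion cascade
#'
#' Applies the exclusion rules in a fixed declared order:
#' (1) subjects with any missing required covariate;
#' (2) liver volume outside the `[q0.001, q0.999]` cohort quantiles —
#'     always flagged for review in the report, excluded when
#'     `auto_exclude_volume` is set;
#' (3) any vertex S2S value outside the plausibility window
#'     (default `[-60, +80]` mm, bracketing the plausible organ range).
#'
#' Quantile thresholds are resolved against the input cohort and echoed as
#' an absolute `volume_range` in `report$rules_resolved`, so that
#' re-applying the resolved rules to the QC output is a no-op.
#'
#' @param covs covariate `data.frame` with a `subject_id` column.
#' @param cohort a `corresponded_cohort` with matching rows, or `NULL` to
#'   skip the S2S rule.
#' @param rules rule list as in `default_qc_rules()`; absolute
#'   `volume_range` overrides the quantile computation.
#' @return List with filtered `covs`, filtered `cohort` and `report`
#'   (class `qc_report`: counts, per-rule id lists, resolved rules).
#' @export
apply_qc <- function(covs, cohort = NULL, rules = default_qc_rules()) {
  n_input <- nrow(covs)
  ids <- covs$subject_id
  if (!is.null(cohort) && nrow(cohort$s2s) != n_input) {
    stop("cohort rows do not match covariate rows")
  }
  rules <- utils::modifyList(default_qc_rules(), rules)

  req <- intersect(rules$required_covariates, names(covs))
  miss <- rowSums(is.na(covs[, req, drop = FALSE])) > 0L
  excluded_missing <- ids[miss]
  keep <- !miss

  vol <- covs$liver_volume
  if (is.null(rules$volume_range)) {
    qs <- stats::quantile(vol[keep], rules$volume_quantiles, na.rm = TRUE,
                          names = FALSE, type = 1)
    rules$volume_range <- qs
  }
  vol_out <- keep & !is.na(vol) &
    (vol < rules$volume_range[1L] | vol > rules$volume_range[2L])
  flagged_volume <- ids[vol_out]
  excluded_volume <- character(0)
  if (isTRUE(rules$auto_exclude_volume)) {
    excluded_volume <- flagged_volume
    keep <- keep & !vol_out
  }

  excluded_s2s <- character(0)
  if (!is.null(cohort)) {
    rng <- rules$s2s_range
    bad <- keep & (apply(cohort$s2s, 1L, min) < rng[1L] |
                   apply(cohort$s2s, 1L, max) > rng[2L])
    excluded_s2s <- ids[bad]
    keep <- keep & !bad
  }

  if (!any(keep)) stop("no subjects remain after quality control")
  covs_out <- covs[keep, , drop = FALSE]
  rownames(covs_out) <- NULL
  cohort_out <- cohort
  if (!is.null(cohort)) {
    cohort_out <- corresponded_cohort(cohort$template,
                                      cohort$s2s[keep, , drop = FALSE],
                                      cohort$subject_ids[keep])
  }
  report <- structure(list(
    n_input = n_input,
    n_excluded_missing = length(excluded_missing),
    n_excluded_volume = length(excluded_volume),
    n_excluded_s2s = length(excluded_s2s),
    n_final = sum(keep),
    excluded_missing = excluded_missing,
    flagged_volume = flagged_volume,
    excluded_volume = excluded_volume,
    excluded_s2s = excluded_s2s,
    rules_resolved = rules
  ), class = "qc_report")
  stopifnot(report$n_input == report$n_final + report$n_excluded_missing +
              report$n_excluded_volume + report$n_excluded_s2s)
  list(covs = covs_out, cohort = cohort_out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d in -> %d excluded missing, %d volume ",
                     "outliers (%d flagged), %d S2S-range -> %d final\n"),
              x$n_input, x$n_excluded_missing, x$n_excluded_volume,
              length(x$flagged_volume), x$n_excluded_s2s, x$n_final))
  invisible(x)
}

#' Write a QC report as JSON plus a readable log
#'
#' @param report a `qc_report`.
#' @param path output JSON path; a `.log` twin is written alongside.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  logp <- sub("\\.json$", ".log", path)
  lines <- c(
    sprintf("input subjects:            %d", report$n_input),
    sprintf("excluded (missing data):   %d  [%s]", report$n_excluded_missing,
            paste(report$excluded_missing, collapse = " ")),
    sprintf("flagged (volume quantile): %d  [%s]", length(report$flagged_volume),
            paste(report$flagged_volume, collapse = " ")),
    sprintf("excluded (volume):         %d", report$n_excluded_volume),
    sprintf("excluded (S2S range):      %d  [%s]", report$n_excluded_s2s,
            paste(report$excluded_s2s, collapse = " ")),
    sprintf("final subjects:            %d", report$n_final))
  writeLines(lines, logp)
  invisible(path)
}
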