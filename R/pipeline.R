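#' Default pipeline configuration
#'
#' One nested list holds every tunable of the pipeline stages: the cohort
#' spec, TFCE/permutation parameters, QC rules, matching calipers and SPCA
#' penalties. A resolved copy is written next to every stage's outputs, and
#' identical config + seed always reproduce identical outputs.
#'
#' @param seed master seed; per-stage substreams are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_subjects = 300L, v_target = 2000L,
                  prevalence = list(liver_disease = 0.013, T2D = 0.053),
                  noise = list(sigma = 2, corr_length = 15)),
    mur = list(model = 2L, interactions = TRUE, standardize = FALSE,
               E = 0.5, H = 2, n_steps = 100L, extent_mode = "area",
               n_perm = 1000L, alpha = 0.05),
    qc = list(auto_exclude_volume = TRUE, s2s_range = c(-60, 80)),
    predict = list(disease = "T2D", variance_target = 0.9,
                   l1 = 1e-3, ridge = 1e-6, calipers = list(age = 1, bmi = 2))
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults.
#'
#' @param path YAML file.
#' @param seed optional seed override.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_pipeline_config()), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

log_stage <- function(dir, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = file.path(dir, "pipeline.log.jsonl"), append = TRUE)
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

#' Simulate stage: write a synthetic cohort to disk
#'
#' Generates the template, covariates, ground-truth effect maps and subject
#' meshes, and writes `template.ply`, `subjects/NNNN.ply`,
#' `covariates.csv`, `truth/effects.vtk` (per-vertex ground-truth maps),
#' `truth/support.csv` and the resolved `spec.yaml`.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @param write_subject_meshes write one PLY per subject (the downstream
#'   stages can also run from `s2s.csv` alone).
#' @return The cohort artefact list, invisibly.
#' @export
cmd_simulate <- function(config = default_pipeline_config(), out_dir,
                         force = FALSE, write_subject_meshes = TRUE) {
  if (config$cohort$n_subjects < 2L) stop("n_subjects must be at least 2")
  prepare_out_dir(out_dir, force)
  t0 <- Sys.time()
  spec <- cohort_spec(n_subjects = config$cohort$n_subjects,
                      v_target = config$cohort$v_target,
                      prevalence = config$cohort$prevalence,
                      noise = config$cohort$noise,
                      seed = config$seed)
  template <- make_template_mesh(spec$v_target, seed = config$seed)
  covs <- sample_covariates(spec$n_subjects, seed = config$seed, spec = spec)
  effects <- make_effect_maps(template, spec, seed = config$seed)
  cohort <- generate_cohort(template, covs, effects, seed = config$seed)
  write_mesh(template, file.path(out_dir, "template.ply"))
  utils::write.csv(covs, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(subject_id = cohort$subject_ids,
                         as.data.frame(round(cohort$s2s, 9))),
                   file.path(out_dir, "s2s.csv"), row.names = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  write_mesh(template, file.path(out_dir, "truth", "effects.vtk"),
             fields = effects$maps, format = "vtk")
  supp <- as.data.frame(lapply(effects$support, as.integer))
  names(supp) <- names(effects$support)
  utils::write.csv(supp, file.path(out_dir, "truth", "support.csv"),
                   row.names = FALSE)
  if (write_subject_meshes) {
    dir.create(file.path(out_dir, "subjects"), showWarnings = FALSE)
    for (i in seq_len(nrow(covs))) {
      write_mesh(cohort_subject_mesh(cohort, i),
                 file.path(out_dir, "subjects", sprintf("%04d.ply", i)))
    }
  }
  write_pipeline_config(config, file.path(out_dir, "spec.yaml"))
  log_stage(out_dir, "simulate", seed = config$seed,
            n_subjects = spec$n_subjects, v = nrow(template$vertices),
            runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(template = template, covs = covs, effects = effects,
                 cohort = cohort))
}

read_cohort_dir <- function(cohort_dir) {
  template <- read_mesh(file.path(cohort_dir, "template.ply"))
  covs <- utils::read.csv(file.path(cohort_dir, "covariates.csv"),
                          stringsAsFactors = FALSE)
  s2s_path <- file.path(cohort_dir, "s2s.csv")
  if (file.exists(s2s_path)) {
    tab <- utils::read.csv(s2s_path, check.names = FALSE)
    s2s <- as.matrix(tab[, -1L, drop = FALSE])
    ids <- tab[[1L]]
  } else {
    files <- sort(list.files(file.path(cohort_dir, "subjects"),
                             pattern = "\\.ply$", full.names = TRUE))
    if (!length(files)) stop("no s2s.csv and no subject meshes in ", cohort_dir)
    normals <- vertex_normals(template)
    s2s <- t(vapply(files, function(f) {
      subj <- rigid_align(read_mesh(f), template)$mesh
      s2s_distance(template, subj, normals = normals)
    }, numeric(nrow(template$vertices))))
    ids <- covs$subject_id
  }
  list(template = template, covs = covs,
       cohort = corresponded_cohort(template, s2s, ids))
}

#' MUR stage: vertex-wise regression, TFCE, permutation FDR
#'
#' Loads a cohort directory produced by [cmd_simulate()] (or laid out the
#' same way), applies QC, builds the configured design, runs
#' [permutation_inference()], and writes per-covariate VTK statistic maps
#' plus the sign-split significance-area CSV.
#'
#' @param config a `pipeline_config`.
#' @param cohort_dir input cohort directory.
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return The `mur_result`, invisibly.
#' @export
cmd_run_mur <- function(config = default_pipeline_config(), cohort_dir,
                        out_dir, force = FALSE) {
  if (config$mur$n_perm < 1L) stop("n_perm must be positive")
  prepare_out_dir(out_dir, force)
  t0 <- Sys.time()
  dat <- read_cohort_dir(cohort_dir)
  qc <- apply_qc(dat$covs, dat$cohort,
                 rules = utils::modifyList(default_qc_rules(), config$qc))
  write_qc_report(qc$report, file.path(out_dir, "qc_report.json"))
  design <- build_design(qc$covs, model = config$mur$model,
                         interactions = isTRUE(config$mur$interactions),
                         standardize = isTRUE(config$mur$standardize))
  params <- tfce_params(E = config$mur$E, H = config$mur$H,
                        n_steps = config$mur$n_steps,
                        extent_mode = config$mur$extent_mode,
                        n_perm = config$mur$n_perm,
                        seed = derive_seed(config$seed, "mur"),
                        alpha = config$mur$alpha)
  result <- permutation_inference(qc$cohort, design, params)
  write_mur_maps(result, file.path(out_dir, "maps"))
  write_area_summary(significance_area(result),
                     file.path(out_dir, "significance_areas.csv"))
  write_pipeline_config(config, file.path(out_dir, "spec.yaml"))
  log_stage(out_dir, "mur", seed = config$seed, n_perm = params$n_perm,
            n_subjects = nrow(qc$covs),
            runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(result)
}

#' Prediction stage: matched-cohort models and DeLong comparison
#'
#' Matches controls to the configured disease's cases under the calipers,
#' fits SPCA shape features on the matched cohort's S2S matrix, selects the
#' modes reaching the cumulative-variance target, evaluates the volume and
#' S2S logistic models with LOOCV, compares their AUCs with DeLong's test
#' and writes `prediction_metrics.csv` (one row per model),
#' `modes_sweep.csv` and `matched_pairs.csv`.
#'
#' @param config a `pipeline_config`.
#' @param cohort_dir input cohort directory.
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @param sweep_modes also compute the AUC-versus-modes curve.
#' @return List with both `prediction_result`s, the DeLong comparison, the
#'   `matched_cohort` and the mode count, invisibly.
#' @export
cmd_predict <- function(config = default_pipeline_config(), cohort_dir,
                        out_dir, force = FALSE, sweep_modes = TRUE) {
  prepare_out_dir(out_dir, force)
  t0 <- Sys.time()
  dat <- read_cohort_dir(cohort_dir)
  covs <- dat$covs
  disease <- config$predict$disease
  if (!disease %in% names(covs)) stop("no disease column ", disease)
  cases <- covs[covs[[disease]] == 1, ]
  if (nrow(cases) < 2L) stop("fewer than 2 cases of ", disease)
  pool <- covs[covs$liver_disease == 0 & covs$T2D == 0, ]
  matched <- match_case_control(cases, pool,
                                calipers = config$predict$calipers)
  if (nrow(matched$pairs) < 2L) stop("fewer than 2 matched pairs")
  ids <- c(matched$pairs$case_id, matched$pairs$control_id)
  ridx <- match(ids, dat$cohort$subject_ids)
  sp <- spca(dat$cohort$s2s[ridx, , drop = FALSE],
             K = min(40L, length(ids) - 2L),
             l1 = config$predict$l1, ridge = config$predict$ridge)
  rownames(sp$scores) <- ids
  k <- tryCatch(select_modes(sp, config$predict$variance_target),
                error = function(e) ncol(sp$scores))
  res_vol <- fit_predict_loocv(matched, covs, features = "volume")
  res_s2s <- fit_predict_loocv(matched, covs, scores = sp$scores,
                               features = "s2s", n_modes = k)
  dl <- delong_test(res_s2s$probs, res_vol$probs, res_vol$labels)
  metrics <- data.frame(
    model = c("volume", "s2s"),
    auc = c(res_vol$auc, res_s2s$auc),
    ci_lo = c(res_vol$auc_ci[1L], res_s2s$auc_ci[1L]),
    ci_hi = c(res_vol$auc_ci[2L], res_s2s$auc_ci[2L]),
    f1 = c(res_vol$f1, res_s2s$f1),
    accuracy = c(res_vol$accuracy, res_s2s$accuracy),
    sensitivity = c(res_vol$sensitivity, res_s2s$sensitivity),
    specificity = c(res_vol$specificity, res_s2s$specificity),
    n_modes = c(0L, k),
    delong_p_vs_volume = c(NA, dl$p_value))
  utils::write.csv(metrics, file.path(out_dir, "prediction_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(matched$pairs,
                         caliper_age = config$predict$calipers$age,
                         caliper_bmi = config$predict$calipers$bmi),
                   file.path(out_dir, "matched_pairs.csv"), row.names = FALSE)
  sweep <- NULL
  if (sweep_modes) {
    sweep <- auc_vs_modes(matched, covs, sp, k_max = min(k, ncol(sp$scores)))
    utils::write.csv(sweep$curve, file.path(out_dir, "modes_sweep.csv"),
                     row.names = FALSE)
  }
  write_pipeline_config(config, file.path(out_dir, "spec.yaml"))
  log_stage(out_dir, "predict", seed = config$seed, disease = disease,
            n_pairs = nrow(matched$pairs), n_modes = k,
            runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(volume = res_vol, s2s = res_s2s, delong = dl,
                 matched = matched, n_modes = k, spca = sp, sweep = sweep))
}
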