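# End-to-end orchestration: simulate or load a campaign, preprocess,
# indices, PCA, PLSDA, mixed models, and a reproducible report. A single
# seed fixes the simulation and the PLSDA split/folds, so re-running a
# configuration reproduces the report byte for byte.

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a campaign from `sim_config`) or
#'   `"manifest"` (load and preprocess files listed in `manifest`).
#' @param sim_config A [leaf_sim_config()] (simulate mode). Its seed is
#'   overridden by `seed`.
#' @param manifest,panel Manifest CSV path and optional panel calibration
#'   (manifest mode).
#' @param seed Integer seed governing simulation and the PLSDA split/folds.
#' @param pca_components Number of principal components to extract.
#' @param pc_model_components Leading PCs entering the mixed models.
#' @param plsda_max_components,plsda_folds,plsda_train_fraction PLSDA tuning
#'   controls.
#' @param indices Vegetation indices to compute (default: all eight;
#'   integrated reflectance is always reported).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "manifest"),
                       sim_config = leaf_sim_config(),
                       manifest = NULL, panel = NULL, seed = 1L,
                       pca_components = 10, pc_model_components = 4,
                       plsda_max_components = 60, plsda_folds = 10,
                       plsda_train_fraction = 0.7,
                       indices = setdiff(index_names(), "INTEGRATED")) {
  mode <- match.arg(mode)
  if (mode == "manifest" && is.null(manifest)) {
    stopf("manifest mode requires a manifest path")
  }
  if (is.na(as.integer(seed))) stopf("a seed is mandatory")
  sim_config$seed <- as.integer(seed)
  structure(list(mode = mode, sim_config = sim_config, manifest = manifest,
                 panel = panel, seed = as.integer(seed),
                 pca_components = pca_components,
                 pc_model_components = pc_model_components,
                 plsda_max_components = plsda_max_components,
                 plsda_folds = plsda_folds,
                 plsda_train_fraction = plsda_train_fraction,
                 indices = indices),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [run_config()] arguments, with
#'   `sim_config` as a nested mapping.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim_config)) {
    for (f in c("pigment_means", "treatment_multipliers",
                "n_total_per_treatment")) {
      if (!is.null(raw$sim_config[[f]])) {
        raw$sim_config[[f]] <- unlist(raw$sim_config[[f]])
      }
    }
    raw$sim_config <- do.call(leaf_sim_config, raw$sim_config)
  }
  do.call(run_config, raw)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: acquire spectra (simulate or load), dataset summary,
#' vegetation indices + integrated reflectance, index mixed models, PCA,
#' PC mixed models, PLSDA tuning/testing, wavelength importance. Rendered
#' files under `out_dir` are terminal artifacts; stages exchange data only
#' in memory.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param write_spectra Also write the (large) wide spectra CSV.
#' @return A list of class `run_report`; see [report_json()] for the
#'   serialized form.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         write_spectra = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set <- run_stage("acquire", {
    if (config$mode == "simulate") simulate_campaign(config$sim_config)
    else load_set(config$manifest, panel = config$panel)
  })
  summary <- run_stage("summary", design_summary(set))
  idx_tbl <- run_stage("indices",
                       index_table(set, c(config$indices, "INTEGRATED")))
  veg_tbl <- idx_tbl[idx_tbl$index_name != "INTEGRATED", ]
  index_fits <- run_stage("index_lmm", fit_all_indices(veg_tbl))
  integrated_fit <- run_stage("integrated_lmm", {
    fit_lmm(idx_tbl[idx_tbl$index_name == "INTEGRATED", ], "value")
  })
  integrated_means <- run_stage("integrated_means", {
    sub <- idx_tbl[idx_tbl$index_name == "INTEGRATED", ]
    grp <- split(sub$value, sub$treatment)
    lapply(grp, function(v) {
      ci <- stats::t.test(v)$conf.int
      list(mean = mean(v), ci_lower = ci[1], ci_upper = ci[2],
           n = length(v))
    })
  })
  pca <- run_stage("pca", pca_fit(set, config$pca_components))
  pc_fits <- run_stage("pc_lmm", fit_pcs(pca, config$pc_model_components))
  tuning <- run_stage("plsda", {
    plsda_tune(set, set$meta$treatment,
               max_components = config$plsda_max_components,
               folds = config$plsda_folds,
               train_fraction = config$plsda_train_fraction,
               seed = config$seed)
  })
  importance <- run_stage("importance", wavelength_importance(tuning$model))
  report <- structure(
    list(config = config, set = set, summary = summary,
         index_table = idx_tbl, index_fits = index_fits,
         integrated_fit = integrated_fit,
         integrated_means = integrated_means,
         pca = pca, pc_fits = pc_fits, plsda = tuning,
         importance = importance,
         provenance = list(package = "leafspec",
                           version = as.character(
                             utils::packageVersion("leafspec")),
                           seed = config$seed)),
    class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir, write_spectra)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d spectra (%s), seed %d\n", x$summary$n_total,
              paste(sprintf("%s %d", names(x$summary$per_treatment),
                            x$summary$per_treatment), collapse = ", "),
              x$config$seed))
  cat(sprintf("  integrated reflectance: aCO2 %.2f, eCO2 %.2f\n",
              x$integrated_means$aCO2$mean, x$integrated_means$eCO2$mean))
  cat(sprintf("  PCA: PC1 %.2f%%, PC1-%d cumulative %.2f%%\n",
              x$pca$ev_fraction[1] * 100, x$config$pc_model_components,
              sum(x$pca$ev_fraction[seq_len(x$config$pc_model_components)]) * 100))
  cat(sprintf("  PLSDA: %d components, CV accuracy %.3f, test accuracy %.3f\n",
              x$plsda$best_n_components, x$plsda$cv_best_accuracy,
              x$plsda$test_stats$accuracy))
  psri <- x$index_fits[x$index_fits$index == "PSRI", ]
  if (nrow(psri)) {
    cat(sprintf("  PSRI eCO2 effect %+.4g (p = %.3g)%s\n", psri$eco2_effect,
                psri$p, if (psri$significant) " *" else ""))
  }
  invisible(x)
}

lmm_fit_record <- function(fit) {
  list(coefficients = fit$coefficients, varcomp = fit$varcomp, n = fit$n,
       reml_criterion = fit$reml_criterion, singular = fit$singular)
}

#' Serializable form of a run report
#'
#' Every number is traceable to a pipeline stage; regenerating the report
#' under the same configuration and seed yields identical JSON.
#'
#' @param report A `run_report`.
#' @return A nested list ready for [jsonlite::toJSON()].
#' @export
report_json <- function(report) {
  pcs <- report$pc_fits
  list(
    provenance = report$provenance,
    dataset = list(
      n_total = report$summary$n_total,
      per_treatment = as.list(report$summary$per_treatment),
      design = report$summary$design),
    integrated = list(
      means = report$integrated_means,
      lmm = lmm_fit_record(report$integrated_fit)),
    pca = list(variance = pca_variance_table(report$pca)),
    pc_models = list(
      univariate = lapply(pcs$univariate, lmm_fit_record),
      pooled = lmm_fit_record(pcs$pooled)),
    indices = as.data.frame(report$index_fits),
    plsda = list(
      best_n_components = report$plsda$best_n_components,
      cv_accuracy = report$plsda$cv_accuracy,
      cv_best_accuracy = report$plsda$cv_best_accuracy,
      test = as.list(report$plsda$test_stats)),
    importance = report$importance
  )
}

#' Write all report artifacts to a directory
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if needed).
#' @param write_spectra Also write the wide spectra CSV.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, write_spectra = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  if (write_spectra) write_spectrum_set(report$set, path("spectra_wide.csv"))
  utils::write.csv(report$index_table, path("index_table.csv"),
                   row.names = FALSE)
  utils::write.csv(pca_variance_table(report$pca), path("pca_variance.csv"),
                   row.names = FALSE)
  utils::write.csv(pca_scores(report$pca), path("pca_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$plsda$cv_accuracy, path("plsda_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(report$importance, path("wavelength_importance.csv"),
                   row.names = FALSE)
  report_table2(report$index_fits, path("index_lmm_table.csv"))
  jsonlite::write_json(report_json(report), path("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Render the index mixed-model summary table
#'
#' Mirrors the conventional reporting layout for per-index mixed models: one
#' row per index with the aCO2 mean and SE, eCO2 effect and SE, t, p (starred
#' at alpha = 0.05), and the tree / tree-by-date / residual variance
#' components with SDs, all formatted to two significant figures. Full
#' precision lives in the JSON report, not this rendering.
#'
#' @param index_fits An `index_lmm_table` from [fit_all_indices()] (or a
#'   `run_report`).
#' @param path Optional CSV output path.
#' @return The formatted data frame, invisibly when `path` is given.
#' @export
report_table2 <- function(index_fits, path = NULL) {
  if (inherits(index_fits, "run_report")) {
    index_fits <- index_fits$index_fits
  }
  f2 <- function(v) formatC(signif(v, 2), format = "g", digits = 2)
  out <- data.frame(
    index = index_fits$index,
    aco2_mean = f2(index_fits$aco2_mean),
    aco2_se = f2(index_fits$aco2_se),
    eco2_effect = f2(index_fits$eco2_effect),
    effect_se = f2(index_fits$effect_se),
    t = f2(index_fits$t),
    df = f2(index_fits$df),
    p = paste0(f2(index_fits$p),
               ifelse(index_fits$significant, " *", "")),
    tree_variance = f2(index_fits$var_tree),
    tree_sd = f2(index_fits$sd_tree),
    date_variance = f2(index_fits$var_tree_date),
    date_sd = f2(index_fits$sd_tree_date),
    residual_variance = f2(index_fits$var_residual),
    residual_sd = f2(index_fits$sd_residual),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
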