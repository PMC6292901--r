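# End-to-end pipeline: simulate -> behavior models -> first-level GLM ->
# group map -> network definition -> cPPI connectivity -> segregation /
# reconfiguration metrics and brain-behavior correlations.

#' Pipeline configuration
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param n_subjects cohort size.
#' @param n_rois ROI count of the simulated parcellation.
#' @param fraction top fraction per network for node selection.
#' @param truth a [ground_truth()] (\code{n_rois} is overridden).
#' @param params a [behavior_params()].
#' @param hrf an [hrf_model()].
#' @param demands demand types for connectivity conditions.
#' @param out_dir optional output directory for reports.
#' @return list of class \code{wm_config}.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 41L, n_rois = 471L,
                            fraction = 0.05, truth = ground_truth(),
                            params = behavior_params(), hrf = hrf_model(),
                            demands = c("set_size", "steps"),
                            out_dir = NULL) {
  truth$n_rois <- as.integer(n_rois)
  if (truth$n_rois < 2L * truth$n_nodes) {
    stop("n_rois too small for the ground-truth networks", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 fraction = fraction, truth = truth, params = params,
                 hrf = hrf, demands = demands, out_dir = out_dir),
            class = "wm_config")
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort (behavior + BOLD), fits the behavioral
#' mixed models, builds first-level designs and computes VIF diagnostics,
#' fits the per-ROI GLMs and the group parametric map, selects the
#' equal-size maintenance/manipulation networks, estimates the per-level
#' cPPI tensors, and derives within/between means, segregation,
#' reconfiguration, difficulty trends and the reconfiguration-criterion
#' correlation.
#'
#' @param config a [pipeline_config()].
#' @param behavior_lrt run the (slower) likelihood-ratio tests in the
#'   behavioral models.
#' @return list of class \code{wm_report}; see elements \code{cohort},
#'   \code{behavior}, \code{vif}, \code{map}, \code{partition},
#'   \code{tensors}, \code{metrics}, \code{reconfiguration},
#'   \code{brain_behavior}, \code{trends}.
#' @export
run_pipeline <- function(config = pipeline_config(), behavior_lrt = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("simulate", generate_cohort(
    n_subjects = config$n_subjects, seed = config$seed,
    params = config$params, truth = config$truth, timeseries = TRUE,
    hrf = config$hrf))
  behavior <- stage("behavior", list(
    accuracy = fit_accuracy_model(cohort$trials, lrt = behavior_lrt),
    rt = fit_rt_model(cohort$trials, lrt = behavior_lrt)))

  designs <- vector("list", config$n_subjects)
  fits <- vector("list", config$n_subjects)
  vifs <- matrix(NA_real_, config$n_subjects, 2,
                 dimnames = list(NULL, c("delay_x_set", "delay_x_steps")))
  for (s in seq_len(config$n_subjects)) {
    tab <- cohort$trials[cohort$trials$subject == s, , drop = FALSE]
    b <- cohort$bundles[[s]]
    designs[[s]] <- stage("design", build_design(
      tab, config$hrf, confounds = b$confounds, n_vol = b$n_vol, tr = b$tr))
    vifs[s, ] <- stage("vif", compute_vif(designs[[s]]))
    fits[[s]] <- stage("glm", fit_glm(b, designs[[s]]))
  }
  map <- stage("groupmap", group_parametric_map(fits))
  partition <- stage("networks", select_top_nodes(map, config$fraction))
  nodes <- c(partition$maintenance, partition$manipulation)

  tensors <- vector("list", config$n_subjects)
  metrics <- list()
  recon <- data.frame()
  for (s in seq_len(config$n_subjects)) {
    tab <- cohort$trials[cohort$trials$subject == s, , drop = FALSE]
    tensors[[s]] <- stage("connectivity", condition_tensor(
      cohort$bundles[[s]], nodes, tab, config$hrf, demands = config$demands))
    for (dm in config$demands) {
      states <- tensors[[s]]$matrices[paste0(dm, "_", 1:4)]
      for (lv in 1:4) {
        wb <- within_between_means(states[[lv]], partition)
        metrics[[length(metrics) + 1L]] <- data.frame(
          subject = s, demand = dm, level = lv,
          z_within_maint = wb$z_within_maint,
          z_within_manip = wb$z_within_manip,
          z_between = wb$z_between,
          segregation_maint = segregation(wb$z_within_maint, wb$z_between),
          segregation_manip = segregation(wb$z_within_manip, wb$z_between))
      }
      for (sub in c("between", "within_maintenance", "within_manipulation")) {
        rec <- reconfiguration(states, partition, subset = sub)
        recon <- rbind(recon, data.frame(
          subject = s, demand = dm, subset = sub, value = rec$value))
      }
    }
  }
  metrics <- do.call(rbind, metrics)

  criterion <- vapply(cohort$subjects, `[[`, numeric(1), "criterion_set_size")
  brain_behavior <- list()
  for (dm in config$demands) {
    bt <- recon$value[recon$demand == dm & recon$subset == "between"]
    brain_behavior[[dm]] <- stage("metrics",
      behavior_correlation(bt, criterion))
  }
  trends <- list()
  for (dm in config$demands) {
    md <- metrics[metrics$demand == dm, ]
    trends[[dm]] <- list(
      segregation_maint = difficulty_trend(data.frame(
        subject = md$subject, level = md$level, metric = md$segregation_maint)),
      between = difficulty_trend(data.frame(
        subject = md$subject, level = md$level, metric = md$z_between)))
  }

  report <- structure(list(
    config = config, cohort = cohort, behavior = behavior,
    designs = designs, vif = colMeans(vifs), vif_by_subject = vifs,
    map = map, partition = partition, tensors = tensors,
    metrics = metrics, reconfiguration = recon,
    brain_behavior = brain_behavior, trends = trends,
    criterion = criterion), class = "wm_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.wm_report <- function(x, ...) {
  cat("Working-memory network pipeline report\n")
  cat(sprintf("  subjects: %d, ROIs: %d, networks: %d + %d nodes\n",
              length(x$cohort$subjects), x$config$truth$n_rois,
              length(x$partition$maintenance),
              length(x$partition$manipulation)))
  cat(sprintf("  mean VIF: set size %.2f, sorting steps %.2f\n",
              x$vif["delay_x_set"], x$vif["delay_x_steps"]))
  agg <- stats::aggregate(cbind(z_within_maint, z_within_manip, z_between) ~
                            demand + level, x$metrics, mean)
  print(agg, digits = 3)
  for (dm in names(x$brain_behavior)) {
    bb <- x$brain_behavior[[dm]]
    cat(sprintf("  reconfiguration~criterion (%s): r = %.3f, p = %.3g\n",
                dm, bb$r, bb$p))
  }
  invisible(x)
}

#' Write the pipeline report to disk
#'
#' Tidy TSV of the per-subject metrics and a JSON summary (VIFs,
#' partition, reconfiguration, correlations, trend tests).
#'
#' @param report a \code{wm_report}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$reconfiguration,
                     file.path(dir, "reconfiguration.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    seed = report$config$seed,
    vif = as.list(report$vif),
    partition = list(fraction = report$partition$fraction,
                     maintenance = report$partition$maintenance,
                     manipulation = report$partition$manipulation),
    brain_behavior = report$brain_behavior,
    trends = report$trends),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
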