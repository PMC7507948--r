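# End-to-end pipeline: cohort -> boundary conditions -> network solve ->
# per-animal vFPP -> agreement and diagnostic reports.

#' Pipeline configuration
#'
#' @param tree tree template ("canonical" or a \code{vessel_tree} /
#'   path to a tree JSON).
#' @param params group parameters ("paper_defaults" uses
#'   \code{\link{default_group_params}()}).
#' @param n_per_group animals per group (default 5).
#' @param seed integer seed.
#' @param mode cohort mode (see \code{\link{generate_cohort}}).
#' @param p_ref absolute reference pressure (mmHg) used in table_emulation
#'   mode; forward_consistent records carry their own.
#' @param cv_diameter,cv_velocity Doppler noise CVs applied to the
#'   measurements before fitting (0 = noise-free).
#' @param threshold portal-hypertension threshold, mmHg (default 12).
#' @param alpha CI level.
#' @param mean_factor mean/max velocity ratio.
#' @param out optional output directory; when set, \code{run_pipeline}
#'   writes cohort CSV, vFPP CSV, JSON reports, VTK pressure fields and a
#'   log there.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(tree = "canonical", params = "paper_defaults",
                            n_per_group = 5L, seed = 1L,
                            mode = "forward_consistent",
                            p_ref = 0, cv_diameter = 0, cv_velocity = 0,
                            threshold = 12, alpha = 0.05,
                            mean_factor = 0.7, out = NULL) {
  if (threshold <= 0) pf_stop("'threshold' must be > 0", "pf_config_error")
  if (n_per_group < 1L) pf_stop("'n_per_group' must be >= 1", "pf_config_error")
  if (is.character(tree)) {
    tree <- if (identical(tree, "canonical")) canonical_tree() else read_tree(tree)
  }
  if (identical(params, "paper_defaults")) params <- default_group_params()
  structure(list(tree = tree, params = params, n_per_group = n_per_group,
                 seed = as.integer(seed), mode = mode, p_ref = p_ref,
                 cv_diameter = cv_diameter, cv_velocity = cv_velocity,
                 threshold = threshold, alpha = alpha,
                 mean_factor = mean_factor, out = out),
            class = "pipeline_config")
}

#' Run the full estimation pipeline
#'
#' Generates (or perturbs) a cohort, fits the flow model to every animal,
#' and computes the agreement and diagnostic reports of virtual versus
#' invasive FPP.  Deterministic for a fixed config + seed; the returned
#' report carries a provenance hash over both.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param seed optional override of \code{config$seed}.
#' @return object of class \code{run_report}: per-animal table
#'   (\code{animals}), \code{agreement} (\code{agreement_report}),
#'   \code{diagnostics} (\code{diagnostic_report}), \code{provenance}.
#' @examples
#' rep <- run_pipeline(pipeline_config(n_per_group = 2, seed = 11))
#' rep$agreement$bias  # 0 at zero noise
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL) {
  if (!inherits(config, "pipeline_config"))
    pf_stop("'config' must be a pipeline_config", "pf_config_error")
  if (!is.null(seed)) config$seed <- as.integer(seed)

  log_lines <- character(0)
  logi <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(paste0("INFO ", fmt), ...))
  }

  logi("stage=cohort seed=%d mode=%s n_per_group=%d", config$seed,
       config$mode, config$n_per_group)
  cohort <- generate_cohort(params = config$params,
                            n_per_group = config$n_per_group,
                            seed = config$seed, mode = config$mode,
                            tree_template = config$tree,
                            mean_factor = config$mean_factor)
  if (config$cv_diameter > 0 || config$cv_velocity > 0) {
    cohort <- add_doppler_noise(cohort, config$cv_diameter,
                                config$cv_velocity, seed = config$seed)
    logi("stage=noise cv_d=%.3f cv_v=%.3f", config$cv_diameter,
         config$cv_velocity)
  }

  ids <- cohort$animals$animal_id
  vfpp_v <- numeric(length(ids))
  fits <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    rec <- get_animal(cohort, ids[j])
    fit <- tryCatch(
      vfpp(rec, tree = config$tree,
           config = solver_config(p_ref = if (config$mode == "table_emulation")
             config$p_ref else rec$p_ref_mmhg),
           mean_factor = config$mean_factor),
      error = function(e) pf_stop(
        sprintf("stage=solve animal=%s: %s", ids[j], conditionMessage(e)),
        "pf_solver_error"))
    vfpp_v[j] <- fit$vfpp_mmhg
    fits[[j]] <- fit
    logi("stage=solve animal=%s vfpp=%.4f fpp_true=%.4f", ids[j],
         vfpp_v[j], rec$fpp_true_mmhg)
  }

  animals <- data.frame(animal_id = ids, group = cohort$animals$group,
                        fpp_true_mmhg = cohort$animals$fpp_true_mmhg,
                        vfpp_mmhg = vfpp_v, stringsAsFactors = FALSE)
  agreement <- agreement_report(animals$fpp_true_mmhg, animals$vfpp_mmhg,
                                alpha = config$alpha)
  diagnostics <- diagnostic_metrics(animals$vfpp_mmhg,
                                    animals$fpp_true_mmhg > config$threshold,
                                    threshold = config$threshold,
                                    alpha = config$alpha)
  prov <- list(
    hash = pf_hash(list(config[setdiff(names(config), "out")], config$seed)),
    seed = config$seed,
    version = as.character(utils::packageVersion("portoflow")))

  report <- structure(list(animals = animals, agreement = agreement,
                           diagnostics = diagnostics, cohort = cohort,
                           provenance = prov, config = config,
                           log = log_lines),
                      class = "run_report")
  if (!is.null(config$out)) write_run_report(report, config$out, fits)
  report
}

write_run_report <- function(report, out, fits = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(report$cohort, file.path(out, "cohort.csv"))
  utils::write.csv(report$animals, file.path(out, "vfpp.csv"),
                   row.names = FALSE)
  ag <- report$agreement
  jsonlite::write_json(
    list(agreement = ag[setdiff(names(ag), "alpha")],
         diagnostics = unclass(report$diagnostics),
         provenance = report$provenance),
    file.path(out, "reports.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  if (!is.null(fits)) {
    for (f in fits)
      write_flow_vtk(f$solution, f$tree,
                     file.path(out, sprintf("pressure_%s.vtk",
                                            f$record$animal_id)))
  }
  writeLines(report$log, file.path(out, "run.log"))
  invisible(out)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run: %d animals, mode '%s', seed %d, hash %s\n",
              nrow(x$animals), x$config$mode, x$provenance$seed,
              x$provenance$hash))
  print(x$agreement)
  print(x$diagnostics)
  invisible(x)
}

#' @export
summary.run_report <- function(object, ...) {
  print(object)
  cat("\nPer-animal table (mmHg):\n")
  print(transform(object$animals,
                  fpp_true_mmhg = round(fpp_true_mmhg, 3),
                  vfpp_mmhg = round(vfpp_mmhg, 3)), row.names = FALSE)
  invisible(object)
}

#' @export
plot.run_report <- function(x, which = c("bland_altman", "roc"), ...) {
  which <- match.arg(which)
  a <- x$animals
  if (which == "bland_altman") {
    m <- (a$fpp_true_mmhg + a$vfpp_mmhg) / 2
    d <- a$vfpp_mmhg - a$fpp_true_mmhg
    graphics::plot(m, d, xlab = "mean of FPP and vFPP (mmHg)",
                   ylab = "vFPP - FPP (mmHg)",
                   main = "Bland-Altman agreement", ...)
    graphics::abline(h = c(x$agreement$bias, x$agreement$loa_upper,
                           x$agreement$loa_lower),
                     lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  } else {
    lab <- a$fpp_true_mmhg > x$config$threshold
    th <- sort(unique(c(-Inf, a$vfpp_mmhg, Inf)), decreasing = TRUE)
    sens <- vapply(th, function(t) mean(a$vfpp_mmhg[lab] > t), 0)
    fpr <- vapply(th, function(t) mean(a$vfpp_mmhg[!lab] > t), 0)
    graphics::plot(fpr, sens, type = "s", xlab = "1 - specificity",
                   ylab = "sensitivity",
                   main = sprintf("ROC (AUC %.3f)", x$diagnostics$auc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Repeats \code{\link{run_pipeline}} over independent seeds (typically in
#' forward_consistent mode with configured Doppler noise) and aggregates
#' the replicate statistics with Monte-Carlo standard errors.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param n_reps number of replicates (>= 1); ignored if \code{seeds} given.
#' @param seeds optional explicit seed vector.
#' @return object of class \code{recovery_summary}: replicate data frame
#'   \code{reps} (bias, icc, ccc, auc per seed) and a \code{summary} row of
#'   means, medians and Monte-Carlo SEs.
#' @export
recovery_experiment <- function(config = pipeline_config(), n_reps = 20L,
                                seeds = NULL) {
  if (is.null(seeds)) {
    if (n_reps < 1L) pf_stop("'n_reps' must be >= 1", "pf_parameter_error")
    seeds <- config$seed + seq_len(n_reps) - 1L
  }
  reps <- do.call(rbind, lapply(seeds, function(s) {
    r <- run_pipeline(config, seed = s)
    data.frame(seed = s, bias = r$agreement$bias, sd_diff = r$agreement$sd_diff,
               icc = r$agreement$icc, ccc = r$agreement$ccc,
               auc = r$diagnostics$auc)
  }))
  mc_se <- function(v) stats::sd(v) / sqrt(length(v))
  summ <- data.frame(
    stat = c("bias", "icc", "ccc", "auc"),
    mean = c(mean(reps$bias), mean(reps$icc), mean(reps$ccc), mean(reps$auc)),
    median = c(stats::median(reps$bias), stats::median(reps$icc),
               stats::median(reps$ccc), stats::median(reps$auc)),
    mc_se = c(mc_se(reps$bias), mc_se(reps$icc), mc_se(reps$ccc),
              mc_se(reps$auc)))
  structure(list(reps = reps, summary = summ, n_reps = length(seeds),
                 config = config),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d replicates, noise CV (d, v) = (%.3f, %.3f)\n",
              x$n_reps, x$config$cv_diameter, x$config$cv_velocity))
  print(transform(x$summary, mean = signif(mean, 6),
                  median = signif(median, 6), mc_se = signif(mc_se, 3)),
        row.names = FALSE)
  invisible(x)
}
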