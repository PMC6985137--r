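#' Read a longitudinal cognitive/motor score table
#'
#' Expects a CSV in long format with columns `subject_id`, `site`, `group`,
#' `sex`, `age`, `cag`, `task`, `visit_date`, `score`. Visit dates are parsed
#' to fractional years from each subject-task's first visit (column
#' `time_years`).
#'
#' @param path CSV file path.
#' @return A `task_panel` data frame (long format) with attribute `subjects`
#'   (one demographic row per subject).
#' @export
read_cognitive_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "site", "group", "sex", "age", "cag", "task",
                "visit_date", "score")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  key <- paste(tab$subject_id, tab$task, tab$visit_date, sep = "|")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "|", fixed = TRUE)[[1]]
    stop(sprintf("duplicate visit row: subject %s, task %s, visit %s",
                 d[1], d[2], d[3]))
  }
  dates <- as.Date(tab$visit_date)
  if (any(is.na(dates))) stop("unparseable visit_date value(s)")
  tab$visit_date <- dates
  first <- stats::aggregate(list(first_date = dates),
                            by = list(subject_id = tab$subject_id,
                                      task = tab$task), FUN = min)
  tab <- merge(tab, first, by = c("subject_id", "task"), sort = FALSE)
  tab$time_years <- as.numeric(tab$visit_date - tab$first_date) / 365.25
  tab$first_date <- NULL
  tab <- tab[order(tab$subject_id, tab$task, tab$visit_date), ]
  ord <- !duplicated(tab$subject_id)
  subjects <- tab[ord, c("subject_id", "site", "group", "sex", "age", "cag")]
  rownames(tab) <- rownames(subjects) <- NULL
  attr(tab, "subjects") <- subjects
  class(tab) <- c("task_panel", "data.frame")
  tab
}

#' Write an evaluation report as schema-versioned JSON
#'
#' @param report A report list (e.g. the `report` element of a `loso_strat`
#'   fit, or any named list of results).
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  payload <- list(schema_version = "1.0",
                  generated_by = paste0("fcdstrat ",
                                        as.character(utils::packageVersion("fcdstrat"))),
                  report = report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run the full stratification analysis end-to-end
#'
#' Simulate (or accept) a cohort, compute FCD maps with full preprocessing,
#' estimate decline slopes and robust PCs, discretize decline, train LOSO-CV
#' stratifiers per measure, run the carrier-vs-control classifier with
#' test-retest reliability, and optionally the confound-control variants.
#' Writes JSON reports, CSV tables, example NIfTI maps, and a log with
#' versions and seeds to `outdir`.
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created if needed).
#' @param measures Decline measures to stratify on: task names and/or
#'   `"PC1"`..`"PC5"`. Default: every task plus the top 5 carrier-only PCs.
#' @param n_perm,n_boot Resampling sizes for reports.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "fcd", "slopes", "stratify", "group_model", "reliability",
#'   "confounds")`; earlier stages are always implied by later ones.
#' @param confound_variants Run site-harmonized / atrophy-residualized /
#'   motion-detrended stratification variants (slow; default FALSE).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with the main fitted objects and the output
#'   directory.
#' @export
run_pipeline <- function(config = cohort_config(), outdir = tempfile("fcdrun"),
                         measures = NULL, n_perm = 1000L, n_boot = 1000L,
                         stages = c("simulate", "fcd", "slopes", "stratify",
                                    "group_model", "reliability"),
                         confound_variants = FALSE, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("fcdstrat %s | R %s | seed %d | %s\n",
              as.character(utils::packageVersion("fcdstrat")),
              paste(R.version$major, R.version$minor, sep = "."),
              config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)

  res <- list(outdir = outdir, config = config)

  # -- simulate ---------------------------------------------------------
  cohort <- generate_cohort(config)
  panel <- generate_task_scores(cohort, config)
  utils::write.csv(cohort, file.path(outdir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(panel, file.path(outdir, "task_panel.csv"), row.names = FALSE)
  res$cohort <- cohort; res$panel <- panel
  logf("simulate: %d subjects, %d sites, %d panel rows",
       nrow(cohort), config$n_sites, nrow(panel))
  if (!length(setdiff(stages, "simulate"))) return(invisible(res))

  # -- fcd --------------------------------------------------------------
  fcd1 <- fcd_from_cohort(cohort, config, visit = 1L)
  res$fcd_v1 <- fcd1
  need_v2 <- any(c("reliability") %in% stages)
  if (need_v2) res$fcd_v2 <- fcd_from_cohort(cohort, config, visit = 2L)
  utils::write.csv(data.frame(subject_id = rownames(fcd1), fcd1),
                   file.path(outdir, "fcd_visit1.csv"), row.names = FALSE)
  map1 <- structure(list(values = fcd1[1, ], degree = NULL, threshold = 0.7,
                         normalization = "median-ratio", smoothed = FALSE,
                         mask = .grid_mask(config)), class = "fcd_map")
  write_fcd_map(map1, nifti_path = file.path(outdir, "example_fcd_map.nii.gz"))
  logf("fcd: %d x %d feature matrix", nrow(fcd1), ncol(fcd1))
  if (!length(setdiff(stages, c("simulate", "fcd")))) return(invisible(res))

  # -- slopes -----------------------------------------------------------
  slopes_raw <- fit_slopes(panel)
  slopes_cor <- residualize_on_controls(
    slopes_raw, age = cohort$age, sex = cohort$sex,
    control_ids = cohort$subject_id[cohort$group == "control"])
  slopes_nrm <- iqr_normalize(slopes_cor)
  pre <- cohort$group == "preHD"
  pca_all <- robust_pca(slopes_nrm)
  pca_pre <- robust_pca(slopes_nrm[pre, , drop = FALSE])
  pc_scores <- matrix(NA_real_, nrow(cohort), pca_pre$n_components,
                      dimnames = list(cohort$subject_id,
                                      paste0("PC", seq_len(pca_pre$n_components))))
  pc_scores[pre, ] <- predict(pca_pre, slopes_nrm[pre, , drop = FALSE])
  res$slopes <- slopes_cor; res$slopes_normalized <- slopes_nrm
  res$pca_all <- pca_all; res$pca_prehd <- pca_pre; res$pc_scores <- pc_scores
  utils::write.csv(data.frame(subject_id = rownames(slopes_cor), slopes_cor),
                   file.path(outdir, "slopes_corrected.csv"), row.names = FALSE)
  logf("slopes: %d tasks; PC1 variance fraction (carriers) %.2f",
       ncol(slopes_raw), pca_pre$variance_fraction[1])
  if (!length(setdiff(stages, c("simulate", "fcd", "slopes"))))
    return(invisible(res))

  # -- stratify ---------------------------------------------------------
  if ("stratify" %in% stages) {
    if (is.null(measures))
      measures <- c(colnames(slopes_cor),
                    paste0("PC", seq_len(pca_pre$n_components)))
    strat_fits <- list()
    rows <- list()
    for (m in measures) {
      vals <- rep(NA_real_, nrow(cohort))
      if (m %in% colnames(slopes_cor)) vals[pre] <- slopes_cor[pre, m]
      else if (m %in% colnames(pc_scores)) vals[pre] <- pc_scores[pre, m]
      else stop(sprintf("unknown measure '%s'", m))
      labs <- rep(NA_character_, nrow(cohort))
      dl <- discretize_decline(vals[pre], measure = m)
      labs[pre] <- as.character(dl$label)
      fit <- loso_stratify(fcd1[pre, , drop = FALSE], labs[pre],
                           cohort$site[pre], decline_values = vals[pre],
                           n_boot = n_boot, n_perm = n_perm,
                           seed = config$seed)
      strat_fits[[m]] <- fit
      rows[[m]] <- data.frame(measure = m, auc = fit$report$mean_auc,
                              auc_p = fit$report$auc_p,
                              spearman = fit$report$pooled_spearman,
                              spearman_p = fit$report$spearman_p)
      logf("stratify[%s]: AUC %.3f (p %.3g), rho %.3f (p %.3g)", m,
           fit$report$mean_auc, fit$report$auc_p,
           fit$report$pooled_spearman, fit$report$spearman_p)
    }
    strat_table <- do.call(rbind, rows)
    rownames(strat_table) <- NULL
    utils::write.csv(strat_table, file.path(outdir, "stratification_table.csv"),
                     row.names = FALSE)
    write_report(lapply(strat_fits, function(f) f$report),
                 file.path(outdir, "stratification_reports.json"))
    res$stratification <- strat_fits
    res$stratification_table <- strat_table
  }

  # -- group model + reliability ---------------------------------------
  if (any(c("group_model", "reliability") %in% stages)) {
    covars <- data.frame(age = cohort$age, sex = cohort$sex,
                         group = cohort$group, fd_mean = cohort$fd_mean_v1,
                         cag = cohort$cag)
    grp_fit <- loso_stratify(fcd1, cohort$group, cohort$site,
                             covariates = covars, correct_age_sex = TRUE,
                             n_boot = n_boot, n_perm = n_perm,
                             seed = config$seed)
    res$group_model <- grp_fit
    write_report(grp_fit$report, file.path(outdir, "group_model_report.json"))
    logf("group model (preHD vs control): AUC %.3f (p %.3g)",
         grp_fit$report$mean_auc, grp_fit$report$auc_p)

    if ("reliability" %in% stages) {
      fp <- fingerprint(res$fcd_v1, res$fcd_v2)
      dec2 <- predict(grp_fit, res$fcd_v2, sites = cohort$site)
      out1 <- outcome_labels(grp_fit$decision_values > 0, cohort$group)
      out2 <- outcome_labels(dec2 > 0, cohort$group)
      tn <- transition_null(out1, out2, cohort$group, n_perm = n_perm,
                            seed = config$seed)
      res$fingerprint <- fp
      res$transitions <- tn
      write_report(list(identification_rate = fp$identification_rate,
                        chance_level = fp$chance_level,
                        rank_distribution = as.vector(table(fp$ranks)),
                        transition_matrix = tn$observed$P,
                        chance_matrix = tn$chance,
                        p_diagonal = tn$p_diagonal),
                   file.path(outdir, "reliability_report.json"))
      logf("reliability: id rate %.1f%% (chance %.2f%%)",
           100 * fp$identification_rate, 100 * fp$chance_level)
    }
  }

  # -- confound-control variants ---------------------------------------
  if (confound_variants || "confounds" %in% stages) {
    gmc <- generate_gmc(cohort, config)
    covars <- data.frame(age = cohort$age, sex = cohort$sex,
                         group = cohort$group, fd_mean = cohort$fd_mean_v1,
                         cag = cohort$cag)
    m <- if (!is.null(res$stratification)) names(res$stratification)[1]
         else colnames(slopes_cor)[1]
    vals <- rep(NA_real_, nrow(cohort)); vals[pre] <- slopes_cor[pre, 1]
    labs <- rep(NA_character_, nrow(cohort))
    labs[pre] <- as.character(discretize_decline(vals[pre])$label)
    variants <- list(
      harmonized = loso_stratify(fcd1[pre, ], labs[pre], cohort$site[pre],
                                 decline_values = vals[pre],
                                 harmonize_sites = TRUE, n_boot = n_boot,
                                 n_perm = n_perm, seed = config$seed),
      atrophy_controlled = loso_stratify(fcd1[pre, ], labs[pre],
                                         cohort$site[pre],
                                         decline_values = vals[pre],
                                         gmc = gmc$gmc[pre, , drop = FALSE],
                                         n_boot = n_boot, n_perm = n_perm,
                                         seed = config$seed),
      motion_detrended = loso_stratify(fcd1[pre, ], labs[pre],
                                       cohort$site[pre],
                                       decline_values = vals[pre],
                                       covariates = covars[pre, ],
                                       detrend_motion = TRUE,
                                       motion_ref = list(
                                         X = fcd1[!pre, , drop = FALSE],
                                         fd_mean = cohort$fd_mean_v1[!pre],
                                         sites = cohort$site[!pre]),
                                       n_boot = n_boot, n_perm = n_perm,
                                       seed = config$seed),
      gmc_only = gmc_only_classifier(gmc$gmc, cohort$group, cohort$site,
                                     n_boot = n_boot, n_perm = n_perm,
                                     seed = config$seed))
    res$confound_variants <- variants
    write_report(lapply(variants, function(f) f$report),
                 file.path(outdir, "confound_variants_report.json"))
    logf("confound variants on measure %s complete", m)
  }
  invisible(res)
}
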