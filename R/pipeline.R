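# End-to-end orchestration: data (synthetic or on disk) -> behavior scoring
# -> per-subject model fits -> family-level BMS -> BMA -> group statistics,
# with all artifacts written to an output directory.

#' Pipeline configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param data_dir dataset directory (as written by `write_cohort`);
#'   alternatively pass a `cohort` object as `cohort`.
#' @param cohort optional in-memory `cohort`.
#' @param model_ids models to fit (default: all 44; fitting the full space
#'   on a full cohort is expensive - reduced subsets are typical for
#'   simulation studies).
#' @param design the `stimulus_design` of the data.
#' @param fit options from `fit_opts()`.
#' @param mc_samples,seed exceedance Monte-Carlo settings.
#' @param bma_weighting weight source for `bma_within_family`.
#' @param target_soa_ms behavioral scoring SOA.
#' @param exclusion_band medial-perceiver exclusion band.
#' @param fdr_q FDR level for the statistics stage.
#' @param pstg_bottom_up model-space switch.
#' @export
pipeline_config <- function(out_dir, data_dir = NULL, cohort = NULL,
                            model_ids = 1:44,
                            design = stimulus_design(),
                            fit = fit_opts(), mc_samples = 1e6, seed = 1,
                            bma_weighting = "exceedance",
                            target_soa_ms = 133,
                            exclusion_band = c(0.5, 0.5), fdr_q = 0.05,
                            pstg_bottom_up = TRUE) {
  if (is.null(data_dir) && is.null(cohort))
    stop("provide data_dir or cohort", call. = FALSE)
  structure(list(out_dir = out_dir, data_dir = data_dir, cohort = cohort,
                 model_ids = model_ids, design = design, fit = fit,
                 mc_samples = mc_samples, seed = seed,
                 bma_weighting = bma_weighting,
                 target_soa_ms = target_soa_ms,
                 exclusion_band = exclusion_band, fdr_q = fdr_q,
                 pstg_bottom_up = pstg_bottom_up),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: ingest data; score McGurk susceptibility and classify
#' perceivers; build the model space; invert every requested model for
#' every subject; random-effects family inference; Bayesian model
#' averaging within the best family; winning-model identification; group
#' statistics over the averaged couplings. Artifacts (`space.json`,
#' `fits/`, `bms.json`, `bma.tsv`, `suscept.csv`, `stats.csv`,
#' `report.json`) are written under `config$out_dir`; the returned report
#' summarizes ns, winners and warnings. Identical inputs and configuration
#' reproduce identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return The run report (invisibly also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)

  # stage 1: data
  if (!is.null(config$cohort)) {
    data <- list(
      meta = do.call(rbind, lapply(config$cohort$subjects, `[[`, "meta")),
      trials = do.call(rbind, lapply(config$cohort$subjects, `[[`, "trials")),
      ts = stats::setNames(lapply(config$cohort$subjects, `[[`, "ts"),
                           vapply(config$cohort$subjects, `[[`, character(1),
                                  "subject_id")))
  } else {
    data <- read_cohort_data(config$data_dir)
  }
  subjects <- names(data$ts)
  if (length(subjects) == 0) stop("stage data: no time series found",
                                  call. = FALSE)

  # stage 2: behavior
  susc <- vapply(subjects, function(s)
    susceptibility(data$trials, s, config$target_soa_ms), numeric(1))
  records <- classify_perceivers(
    data.frame(subject_id = subjects, susceptibility = susc),
    config$exclusion_band)
  write.csv(records, file.path(config$out_dir, "suscept.csv"),
            row.names = FALSE)
  kept <- records$subject_id[records$group != "excluded"]
  if (length(kept) < length(subjects))
    warnings_log <- c(warnings_log,
                      sprintf("%d medial perceiver(s) excluded",
                              length(subjects) - length(kept)))

  # stage 3: model space
  space <- build_model_space(pstg_bottom_up = config$pstg_bottom_up)
  write_model_space(space, file.path(config$out_dir, "space.json"))
  model_ids <- config$model_ids

  # stage 4: inversion
  fit_dir <- file.path(config$out_dir, "fits")
  dir.create(fit_dir, showWarnings = FALSE)
  fits <- lapply(kept, function(s) {
    lapply(model_ids, function(mid) {
      spec <- space$models[[mid]]
      f <- fit_model(data$ts[[s]], spec, config$design,
                     priors = default_priors(spec), opts = config$fit,
                     subject_id = s)
      write_fit(f, file.path(fit_dir, sprintf("%s_model-%02d.json", s, mid)))
      f
    })
  })
  names(fits) <- kept
  n_unconv <- sum(!vapply(unlist(fits, recursive = FALSE), `[[`,
                          logical(1), "converged"))
  if (n_unconv > 0)
    warnings_log <- c(warnings_log,
                      sprintf("%d fit(s) stopped at max_iter", n_unconv))

  # stage 5: family-level BMS
  L <- t(vapply(fits, function(fs)
    vapply(fs, `[[`, numeric(1), "free_energy"), numeric(length(model_ids))))
  colnames(L) <- as.character(model_ids)
  partition <- lapply(family_partition(space), intersect, model_ids)
  partition <- partition[lengths(partition) > 0]
  fam <- family_level_inference(L, partition, mc_samples = config$mc_samples,
                                seed = config$seed)
  best_family <- select_winning(fam)
  fam_members <- as.character(partition[[best_family]])

  # stage 6: BMA within the best family + winning model
  bma <- bma_within_family(fits, fam$model_level,
                           family_models = fam_members,
                           weighting = config$bma_weighting)
  in_fam <- match(fam_members, as.character(fam$model_level$model_ids))
  win_xp <- fam$model_level$exceedance_prob[in_fam]
  winner <- fam_members[which.max(win_xp)]
  jsonlite::write_json(
    list(level = "family", alpha = fam$alpha,
         expected_prob = fam$expected_prob,
         exceedance_prob = fam$exceedance_prob,
         family_ids = fam$family_ids, best_family = best_family,
         model_alpha = fam$model_level$alpha,
         model_exceedance = fam$model_level$exceedance_prob,
         model_ids = fam$model_level$model_ids, winner = winner,
         seed = config$seed, mc_samples = config$mc_samples),
    file.path(config$out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)
  bma_df <- do.call(rbind, lapply(bma, function(b) {
    vals <- c(flatten_named(b$A_vals, "A"), flatten_named(b$B_vals, "B"))
    cbind(data.frame(subject_id = b$subject_id), as.data.frame(t(vals)))
  }))
  write.table(bma_df, file.path(config$out_dir, "bma.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # stage 7: parameter statistics
  meta <- data$meta[match(kept, data$meta$subject_id), ]
  meta$group <- records$group[match(kept, records$subject_id)]
  stats_tab <- build_stats_table(bma, meta,
                                 records$susceptibility[match(kept,
                                   records$subject_id)],
                                 q = config$fdr_q)
  write_stats_table(stats_tab, file.path(config$out_dir, "stats.csv"))

  report <- list(package_version =
                   as.character(utils::packageVersion("speechdcm")),
                 seed = config$seed,
                 config = config_summary(config),
                 n_subjects_input = length(subjects),
                 n_subjects_analyzed = length(kept),
                 n_strong = sum(meta$group == "strong"),
                 n_weak = sum(meta$group == "weak"),
                 models_fit = model_ids,
                 best_family = best_family,
                 winning_model = as.integer(winner),
                 family_exceedance = stats::setNames(
                   as.list(fam$exceedance_prob), fam$family_ids),
                 warnings = warnings_log)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

flatten_named <- function(M, prefix) {
  idx <- which(row(M) != col(M), arr.ind = TRUE)
  vals <- M[idx]
  names(vals) <- paste(prefix, rownames(M)[idx[, 1]], colnames(M)[idx[, 2]],
                       sep = ".")
  vals
}

config_summary <- function(config) {
  list(model_ids = config$model_ids, mc_samples = config$mc_samples,
       seed = config$seed, bma_weighting = config$bma_weighting,
       target_soa_ms = config$target_soa_ms,
       exclusion_band = config$exclusion_band, fdr_q = config$fdr_q,
       pstg_bottom_up = config$pstg_bottom_up,
       fit = config$fit[c("tol", "max_iter", "fd_step")])
}
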