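# Synthetic-cohort generator: group-structured ground-truth couplings,
# four-region BOLD sessions, behavioral trial tables and demographics with
# the statistical structure the analysis pipeline assumes.

#' Default group-level coupling distributions
#'
#' Per-connection means and SDs of the endogenous (A) and modulatory (B)
#' couplings for strong and weak McGurk perceivers on the winning structure
#' (model 13), together with the sign and significance of each connection's
#' reported correlation with susceptibility. These are the generating
#' distributions for synthetic ground truths.
#'
#' @return Data frame with columns `matrix`, `source`, `target`,
#'   `mean_all`, `sd_all`, `mean_strong`, `sd_strong`, `mean_weak`,
#'   `sd_weak`, `corr_r`, `corr_sig`.
#' @export
default_coupling_params <- function() {
  tab <- rbind(
    c("A", "PrG",  "pSTG",  0.31, 0.11,  0.34, 0.07,  0.26, 0.14,  0.54, 1),
    c("A", "PrG",  "mSTG", -0.32, 0.22, -0.49, 0.13, -0.11, 0.08, -0.77, 1),
    c("A", "PrG",  "FuG",   0.12, 0.16,  0.17, 0.18,  0.06, 0.09,  0.37, 1),
    c("A", "pSTG", "PrG",  -0.15, 0.36, -0.44, 0.18,  0.22, 0.10, -0.74, 1),
    c("A", "pSTG", "mSTG", -0.30, 0.34, -0.56, 0.20,  0.03, 0.15, -0.76, 1),
    c("A", "pSTG", "FuG",  -0.36, 0.29, -0.53, 0.21, -0.15, 0.21, -0.61, 1),
    c("A", "mSTG", "PrG",   0.01, 0.36,  0.31, 0.12, -0.37, 0.12,  0.81, 1),
    c("A", "mSTG", "pSTG",  0.36, 0.16,  0.28, 0.14,  0.46, 0.13, -0.47, 1),
    c("A", "mSTG", "FuG",   0.24, 0.45, -0.13, 0.15,  0.70, 0.17, -0.71, 1),
    c("A", "FuG",  "PrG",  -0.35, 0.18, -0.25, 0.16, -0.48, 0.12,  0.63, 1),
    c("A", "FuG",  "pSTG", -0.35, 0.16, -0.32, 0.18, -0.38, 0.13,  0.17, 0),
    c("A", "FuG",  "mSTG",  0.11, 0.13,  0.13, 0.15,  0.08, 0.11,  0.19, 0),
    c("B", "PrG",  "mSTG", -0.44, 0.66,  0.04, 0.37, -1.03, 0.42,  0.64, 1),
    c("B", "PrG",  "FuG",  -3.10, 1.36, -2.23, 0.66, -4.20, 1.20,  0.67, 1),
    c("B", "mSTG", "PrG",   2.91, 0.94,  2.28, 0.48,  3.71, 0.73, -0.59, 1),
    c("B", "mSTG", "pSTG",  0.97, 1.02,  1.67, 0.55,  0.10, 0.78,  0.69, 1),
    c("B", "FuG",  "PrG",  -0.70, 0.55, -0.37, 0.37, -1.12, 0.43,  0.67, 1),
    c("B", "FuG",  "pSTG",  0.08, 0.56,  0.33, 0.26, -0.24, 0.67,  0.66, 1))
  out <- data.frame(matrix = tab[, 1], source = tab[, 2], target = tab[, 3],
                    stringsAsFactors = FALSE)
  num <- apply(tab[, 4:11], 2, as.numeric)
  colnames(num) <- c("mean_all", "sd_all", "mean_strong", "sd_strong",
                     "mean_weak", "sd_weak", "corr_r", "corr_sig")
  cbind(out, num)
}

#' Synthetic-cohort configuration
#'
#' Defaults encode the study conditions: 25 strong and 20 weak perceivers,
#' model-13 generating structure, group coupling distributions from
#' `default_coupling_params`, the standard block design, demographics of
#' the two groups (age 21.84 +/- 2.115 vs 20.60 +/- 2.257 years, education
#' 15.40 +/- 1.443 vs 15.20 +/- 1.824 years, male fractions 12/25 vs 13/20,
#' mean frame-wise displacement 0.088 +/- 0.051 vs 0.087 +/- 0.040 mm).
#'
#' @param n_strong,n_weak group sizes.
#' @param generating_model_id structure from which data are generated.
#' @param snr signal-to-noise ratio: SD of the session-mean-corrected
#'   noiseless BOLD over the observation noise SD, per region.
#' @param coupling coupling distribution table (see
#'   `default_coupling_params`).
#' @param self_connection ground-truth self-coupling (Hz, negative).
#' @param c_weight driving-input weight at mSTG and FuG.
#' @param design a `stimulus_design`.
#' @param link behavior link: `slope` (logit units per unit coupling
#'   z-score), `noise_sd` (logit-scale subject noise), `curve_width_ms`
#'   (SOA tuning width of the fusion curve).
#' @param null_groups generate both groups from the all-participant
#'   distribution and cut the behavior link (calibration studies).
#' @param pstg_bottom_up keep the bottom-up pSTG modulations in the
#'   generating structure.
#' @export
cohort_config <- function(n_strong = 25, n_weak = 20,
                          generating_model_id = 13, snr = 1,
                          coupling = default_coupling_params(),
                          self_connection = -2, c_weight = 0.5,
                          design = stimulus_design(),
                          link = list(slope = 1.2, noise_sd = 0.3,
                                      curve_width_ms = 100),
                          null_groups = FALSE,
                          pstg_bottom_up = TRUE) {
  stopifnot(n_strong >= 2, n_weak >= 2, snr > 0, self_connection < 0)
  structure(list(n_strong = n_strong, n_weak = n_weak,
                 generating_model_id = generating_model_id, snr = snr,
                 coupling = coupling, self_connection = self_connection,
                 c_weight = c_weight, design = design, link = link,
                 null_groups = null_groups,
                 pstg_bottom_up = pstg_bottom_up),
            class = "cohort_config")
}

draw_matrices <- function(coupling, group, spec, self_connection, c_weight,
                          null_groups) {
  rn <- canonical_region_names
  mcol <- if (null_groups) "mean_all" else paste0("mean_", group)
  scol <- if (null_groups) "sd_all" else paste0("sd_", group)
  A <- matrix(0, 4, 4, dimnames = list(rn, rn))
  B <- matrix(0, 4, 4, dimnames = list(rn, rn))
  for (k in seq_len(nrow(coupling))) {
    row <- coupling[k, ]
    val <- rnorm(1, row[[mcol]], row[[scol]])
    if (row$matrix == "A") A[row$target, row$source] <- val
    else B[row$target, row$source] <- val
  }
  diag(A) <- self_connection
  # restrict to the generating structure
  A[spec$A == 0 & row(A) != col(A)] <- 0
  B[spec$B == 0] <- 0
  C <- c(0, 0, c_weight, c_weight)
  list(A = A, B = B, C = C)
}

# sign-weighted coupling z-score used by the behavior link: deviations from
# the all-participant means along the connections with significant reported
# correlations, weighted by the correlation sign
behavior_score <- function(A, B, coupling) {
  sel <- coupling[coupling$corr_sig == 1, ]
  z <- vapply(seq_len(nrow(sel)), function(k) {
    row <- sel[k, ]
    val <- if (row$matrix == "A") A[row$target, row$source] else
      B[row$target, row$source]
    sign(row$corr_r) * (val - row$mean_all) / row$sd_all
  }, numeric(1))
  mean(z)
}

#' Ground-truth parameters and behavioral targets for a cohort
#'
#' Draws per-subject coupling strengths from the group-specific Gaussian
#' distributions, resampling until the effective matrices A + uB are stable
#' for u in \{0, 1\} (at most 1000 attempts per subject), and maps each
#' subject's sign-weighted coupling z-score through a logistic link to a
#' target susceptibility. Targets are truncated to the side of 0.5 that
#' matches the group label so that group membership and behavior stay
#' consistent.
#'
#' @param config a `cohort_config`.
#' @param seed RNG seed.
#' @return List of subjects, each with `subject_id`, `group`, `params`
#'   (`dcm_params`), `score` and `susceptibility_target`.
#' @export
generate_ground_truth <- function(config = cohort_config(), seed = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  space <- build_model_space(pstg_bottom_up = config$pstg_bottom_up)
  spec <- space$models[[config$generating_model_id]]
  groups <- c(rep("strong", config$n_strong), rep("weak", config$n_weak))
  lapply(seq_along(groups), function(i) {
    grp <- groups[i]
    for (attempt in seq_len(1000)) {
      m <- draw_matrices(config$coupling, grp, spec, config$self_connection,
                         config$c_weight, config$null_groups)
      p <- tryCatch(dcm_params(spec, m$A, m$B, m$C, check_stability = TRUE),
                    error = function(e) NULL)
      if (!is.null(p)) break
      p <- NULL
    }
    if (is.null(p))
      stop("could not draw stable parameters after 1000 attempts",
           call. = FALSE)
    score <- behavior_score(p$A_vals, p$B_vals, config$coupling)
    slope <- if (config$null_groups) 0 else config$link$slope
    eta <- slope * score + rnorm(1, 0, config$link$noise_sd)
    target <- stats::plogis(eta)
    if (!config$null_groups)
      target <- if (grp == "strong") pmin(pmax(target, 0.52), 0.98) else
        pmin(pmax(target, 0.02), 0.48)
    list(subject_id = sprintf("sub-%02d", i), group = grp, params = p,
         score = score, susceptibility_target = target)
  })
}

#' Behavioral trials for one subject
#'
#' 10 trials at each of the 29 SOAs. The /ta/ (fusion) probability follows
#' a Gaussian-in-SOA curve peaking at +133 ms with peak value equal to the
#' target susceptibility; non-fusion responses split 3:1 between /pa/
#' (auditory capture) and /ka/ (visual capture). With `sample = FALSE` the
#' per-SOA counts are the rounded expectations (no binomial noise).
#'
#' @param target_susceptibility peak fusion probability in [0, 1].
#' @param subject_id label for the rows.
#' @param n_trials trials per SOA.
#' @param width_ms SOA tuning width (SD of the Gaussian curve, ms).
#' @param peak_soa_ms peak location (ms).
#' @param sample draw binomial counts (TRUE) or use rounded expectations.
#' @param seed optional RNG seed.
#' @return Trial table (subject_id, soa_ms, trial, response).
#' @export
generate_behavioral_trials <- function(target_susceptibility,
                                       subject_id = "sub-01", n_trials = 10,
                                       width_ms = 100, peak_soa_ms = 133,
                                       sample = TRUE, seed = NULL) {
  stopifnot(target_susceptibility >= 0, target_susceptibility <= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  grid <- soa_grid()
  p_ta <- target_susceptibility *
    exp(-(grid - peak_soa_ms)^2 / (2 * width_ms^2))
  n_ta <- if (sample) rbinom(length(grid), n_trials, p_ta) else
    round(n_trials * p_ta)
  n_rest <- n_trials - n_ta
  n_ka <- if (sample) rbinom(length(grid), n_rest, 0.25) else
    round(n_rest * 0.25)
  resp <- unlist(lapply(seq_along(grid), function(k) {
    r <- c(rep("ta", n_ta[k]), rep("ka", n_ka[k]),
           rep("pa", n_rest[k] - n_ka[k]))
    if (sample) r[sample.int(n_trials)] else r
  }))
  data.frame(subject_id = subject_id,
             soa_ms = rep(grid, each = n_trials),
             trial = rep(seq_len(n_trials), times = length(grid)),
             response = resp, stringsAsFactors = FALSE)
}

truncnorm1 <- function(mean, sd, lo, hi) {
  for (i in seq_len(100)) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Generate a complete synthetic study dataset
#'
#' For each subject: ground-truth couplings (group-structured, stable),
#' three sessions of four-region BOLD at the configured SNR, a behavioral
#' trial table realizing the target susceptibility, and demographics.
#' Observation noise SD is set per region to the SD of the session-mean-
#' corrected noiseless signal divided by `snr`. Everything derives from the
#' single `seed`.
#'
#' @param config a `cohort_config`.
#' @param seed RNG seed.
#' @param timeseries also simulate BOLD (set FALSE for behavior/statistics
#'   studies that only need the ground truth).
#' @return A `cohort`: list with `subjects` (each holding `params`, `ts`,
#'   `trials`, `meta`, `susceptibility_target`), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            timeseries = TRUE) {
  truth <- generate_ground_truth(config, seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed + 1L)
  design <- config$design
  subjects <- lapply(truth, function(su) {
    grp <- su$group
    age_m <- if (grp == "strong") 21.84 else 20.60
    age_s <- if (grp == "strong") 2.115 else 2.257
    edu_m <- if (grp == "strong") 15.40 else 15.20
    edu_s <- if (grp == "strong") 1.443 else 1.824
    male_p <- if (grp == "strong") 12 / 25 else 13 / 20
    fd_m <- if (grp == "strong") 0.088 else 0.087
    fd_s <- if (grp == "strong") 0.051 else 0.040
    meta <- data.frame(subject_id = su$subject_id, group = grp,
                       age = round(truncnorm1(age_m, age_s, 18, 28)),
                       gender = rbinom(1, 1, male_p),
                       education = round(truncnorm1(edu_m, edu_s, 12, 20)),
                       mean_fd = truncnorm1(fd_m, fd_s, 0.005, 0.3))
    ts <- NULL
    if (timeseries) {
      clean <- simulate_timeseries(su$params, design, noise_sd = 0)
      Y <- as.matrix(as.data.frame(clean)[, canonical_region_names])
      X0 <- confound_matrix(design)
      Q <- qr.Q(qr(X0))
      Yc <- Y - Q %*% crossprod(Q, Y)
      noise_sd <- apply(Yc, 2, sd) / config$snr
      ts <- clean
      for (r in 1:4) {
        col <- canonical_region_names[r]
        ts[[col]] <- ts[[col]] + rnorm(nrow(ts), 0, noise_sd[r])
      }
      attr(ts, "noise_sd") <- noise_sd
    }
    trials <- generate_behavioral_trials(su$susceptibility_target,
                                         subject_id = su$subject_id,
                                         width_ms = config$link$curve_width_ms)
    c(su, list(meta = meta, ts = ts, trials = trials))
  })
  structure(list(subjects = subjects, config = config, seed = seed),
            class = "cohort")
}

#' Write / read a cohort dataset to a directory
#'
#' Layout: `meta.csv`, `trials.csv`, `events.tsv` (+ per-session files),
#' `ts/<subject>.tsv` with JSON sidecars, and a `truth.json` ground-truth
#' sidecar that the analysis pipeline never reads.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ts"), showWarnings = FALSE)
  meta <- do.call(rbind, lapply(cohort$subjects, `[[`, "meta"))
  write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  trials <- do.call(rbind, lapply(cohort$subjects, `[[`, "trials"))
  write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE,
            quote = FALSE)
  write_events(cohort$config$design, file.path(dir, "events.tsv"))
  hemo <- hemodynamic_params()
  for (su in cohort$subjects) {
    if (!is.null(su$ts))
      write_timeseries(su$ts, file.path(dir, "ts",
                                        paste0(su$subject_id, ".tsv")),
                       metadata = list(hemodynamics = unclass(hemo),
                                       seed = cohort$seed))
  }
  truth <- lapply(cohort$subjects, function(su)
    list(subject_id = su$subject_id, group = su$group,
         susceptibility_target = su$susceptibility_target,
         A_vals = su$params$A_vals, B_vals = su$params$B_vals,
         C_vals = as.list(su$params$C_vals)))
  jsonlite::write_json(list(seed = cohort$seed,
                            generating_model_id =
                              cohort$config$generating_model_id,
                            snr = cohort$config$snr, subjects = truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_data <- function(dir) {
  meta <- read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  trials <- read_trials(file.path(dir, "trials.csv"))
  ts_files <- list.files(file.path(dir, "ts"), pattern = "\\.tsv$",
                         full.names = TRUE)
  ts <- lapply(ts_files, read_timeseries)
  names(ts) <- sub("\\.tsv$", "", basename(ts_files))
  list(meta = meta, trials = trials, ts = ts)
}
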