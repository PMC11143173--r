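#' Hemodynamic constants for the Balloon-Windkessel observation model
#'
#' Standard literature values; the neuronal model is agnostic to them and
#' they are reported in all output metadata. Units: `kappa` (signal decay,
#' 1/s), `gamma` (autoregulation, 1/s), `tau` (mean transit time, s),
#' `alpha` (vessel stiffness exponent), `E0` (resting oxygen extraction
#' fraction), `V0` (resting venous blood volume fraction).
#'
#' @export
hemodynamic_params <- function(kappa = 0.64, gamma = 0.32, tau = 2.0,
                               alpha = 0.32, E0 = 0.4, V0 = 0.04) {
  stopifnot(kappa > 0, gamma > 0, tau > 0,
            alpha > 0, alpha < 1, E0 > 0, E0 < 1, V0 > 0, V0 < 1)
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 E0 = E0, V0 = V0), class = "hemo_params")
}

#' Real-valued DCM parameters for one subject-model
#'
#' Couples a binary `model_spec` structure with real coupling strengths in
#' Hz. Entries of `A_vals`/`B_vals` must be zero wherever the structure is
#' zero (off-diagonal), the diagonal of `A_vals` must be strictly negative
#' (self-inhibition), and — for synthetic ground truths — the effective
#' matrix A + u B must be stable for u in \{0, 1\}.
#'
#' @param spec a `model_spec` giving the zero pattern.
#' @param A_vals,B_vals 4x4 numeric matrices (Hz).
#' @param C_vals length-4 numeric driving weights.
#' @param hemo per-region list of `hemo_params` (a single set is recycled).
#' @param check_stability error if A + uB has a non-negative spectral
#'   abscissa for u in \{0,1\}.
#' @return A `dcm_params` object.
#' @export
dcm_params <- function(spec, A_vals, B_vals, C_vals,
                       hemo = hemodynamic_params(), check_stability = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  A_vals <- as.matrix(A_vals); B_vals <- as.matrix(B_vals)
  rn <- canonical_region_names
  dimnames(A_vals) <- dimnames(B_vals) <- list(rn, rn)
  C_vals <- stats::setNames(as.numeric(C_vals), rn)
  off <- row(A_vals) != col(A_vals)
  if (any(A_vals[off & spec$A == 0] != 0))
    stop("A_vals has a nonzero entry outside the model structure", call. = FALSE)
  if (any(B_vals[spec$B == 0] != 0))
    stop("B_vals has a nonzero entry outside the model structure", call. = FALSE)
  if (any(C_vals[spec$C == 0] != 0))
    stop("C_vals drives a region outside the model structure", call. = FALSE)
  if (any(diag(A_vals) >= 0))
    stop("diagonal of A_vals must be strictly negative (self-inhibition)",
         call. = FALSE)
  if (inherits(hemo, "hemo_params")) hemo <- rep(list(hemo), 4)
  stopifnot(length(hemo) == 4)
  p <- structure(list(A_vals = A_vals, B_vals = B_vals, C_vals = C_vals,
                      hemo = hemo, structure = spec), class = "dcm_params")
  if (check_stability && stability_check(p) >= 0)
    stop("unstable parameters: max Re(eigen(A + uB)) >= 0 for u in {0,1}",
         call. = FALSE)
  p
}

#' Spectral abscissa of the effective coupling matrix
#'
#' @param params a `dcm_params` object (or a plain matrix, taken as A).
#' @param u input values at which to evaluate A + uB (default 0 and 1).
#' @return Maximum over `u` of the largest real part of the eigenvalues of
#'   A + uB; negative means stable.
#' @export
stability_check <- function(params, u = c(0, 1)) {
  if (is.matrix(params)) {
    A <- params; B <- matrix(0, nrow(A), ncol(A))
  } else {
    A <- params$A_vals; B <- params$B_vals
  }
  max(vapply(u, function(ui)
    max(Re(eigen(A + ui * B, only.values = TRUE)$values)), numeric(1)))
}

#' Bilinear neuronal drift (reference implementation)
#'
#' dz/dt = (A + u B) z + C u. The compiled integrator uses the same
#' expression; this plain-R version backs the unit tests.
#'
#' @param z length-4 neuronal state.
#' @param u scalar input.
#' @param params a `dcm_params` object.
#' @export
neural_drift <- function(z, u, params) {
  if (!all(is.finite(z)) || !is.finite(u))
    stop("non-finite state or input", call. = FALSE)
  as.numeric((params$A_vals + u * params$B_vals) %*% z + params$C_vals * u)
}

#' Balloon-Windkessel drift (reference implementation)
#'
#' States per region: vasodilatory signal s, inflow f, venous volume v,
#' deoxyhemoglobin q. At rest (z = 0, s = 0, f = v = q = 1) the drift is 0.
#'
#' @param h list with numeric vectors `s`, `f`, `v`, `q` (one per region).
#' @param z neuronal states.
#' @param hemo a single `hemo_params` (applied to all regions) or a list of
#'   4.
#' @return List of derivatives `ds`, `df`, `dv`, `dq`.
#' @export
hemodynamic_drift <- function(h, z, hemo = hemodynamic_params()) {
  if (inherits(hemo, "hemo_params")) hemo <- rep(list(hemo), length(z))
  if (any(h$f <= 0) || any(h$v <= 0) || any(h$q <= 0))
    stop("hemodynamic states f, v, q must stay positive", call. = FALSE)
  n <- length(z)
  ds <- df <- dv <- dq <- numeric(n)
  for (r in seq_len(n)) {
    hp <- hemo[[r]]
    ds[r] <- z[r] - hp$kappa * h$s[r] - hp$gamma * (h$f[r] - 1)
    df[r] <- h$s[r]
    fout <- h$v[r]^(1 / hp$alpha)
    ef <- 1 - (1 - hp$E0)^(1 / h$f[r])
    dv[r] <- (h$f[r] - fout) / hp$tau
    dq[r] <- (h$f[r] * ef / hp$E0 - fout * h$q[r] / h$v[r]) / hp$tau
  }
  list(ds = ds, df = df, dv = dv, dq = dq)
}

#' BOLD observation equation
#'
#' y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)) with k1 = 7 E0, k2 = 2,
#' k3 = 2 E0 - 0.2; zero at the resting point v = q = 1.
#'
#' @param v,q venous volume and deoxyhemoglobin content (positive).
#' @param hemo a `hemo_params`.
#' @return Percent signal change (same shape as `v`).
#' @export
bold_observation <- function(v, q, hemo = hemodynamic_params()) {
  if (any(v <= 0) || any(q <= 0))
    stop("v and q must be positive", call. = FALSE)
  k1 <- 7 * hemo$E0; k2 <- 2; k3 <- 2 * hemo$E0 - 0.2
  hemo$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Block-design stimulus timing
#'
#' Encodes the study design: `n_sessions` sessions of
#' `n_volumes + discard_volumes` volumes at repetition time `tr`; after an
#' initial `fixation_s` of rest, `blocks_per_session` contiguous blocks of
#' `block_duration` s; each block holds `trials_per_block` trials of
#' `trial_duration` s stimulation followed by `trial_gap` s fixation. The
#' first `discard_volumes` volumes are dropped from the output (steady-state
#' magnetization), so the default yields 189 retained volumes per session.
#'
#' The driving input u(t) is a 0/1 indicator on the microtime grid. With
#' `input_unit = "trial"` (default) u follows the trial on/off train; with
#' `"block"` u covers whole blocks. Because the blocks are contiguous, the
#' block-level boxcar is constant over the retained window and is provided
#' only for comparison.
#'
#' @param tr repetition time (s).
#' @param n_volumes retained volumes per session.
#' @param n_sessions number of sessions.
#' @param blocks_per_session number of stimulation blocks.
#' @param block_duration block length (s).
#' @param block_onsets list (per session) of block start times (s, from
#'   session start); defaults to contiguous blocks after the fixation.
#' @param trial_duration,trial_gap,trials_per_block trial-level timing (s).
#' @param fixation_s initial fixation (s).
#' @param discard_volumes dummy volumes dropped from each session.
#' @param microtime_dt integration step (s); default tr/16.
#' @param input_unit "trial" or "block".
#' @param mean_center subtract the mean of u over the session (off by
#'   default).
#' @return A `stimulus_design` object.
#' @export
stimulus_design <- function(tr = 2, n_volumes = 189, n_sessions = 3,
                            blocks_per_session = 18, block_duration = 21,
                            block_onsets = NULL,
                            trial_duration = 2, trial_gap = 1,
                            trials_per_block = 7,
                            fixation_s = 20, discard_volumes = 10,
                            microtime_dt = tr / 16,
                            input_unit = c("trial", "block"),
                            mean_center = FALSE) {
  input_unit <- match.arg(input_unit)
  total_volumes <- n_volumes + discard_volumes
  session_s <- total_volumes * tr
  if (is.null(block_onsets))
    block_onsets <- rep(list(fixation_s + block_duration *
                               (seq_len(blocks_per_session) - 1)), n_sessions)
  stopifnot(length(block_onsets) == n_sessions)
  for (on in block_onsets) {
    if (length(on) != blocks_per_session)
      stop("each session needs exactly blocks_per_session onsets", call. = FALSE)
    if (any(on < 0) || any(on + block_duration > session_s + 1e-9))
      stop("block onsets must lie within the session", call. = FALSE)
    if (is.unsorted(on) || any(diff(on) < block_duration - 1e-9))
      stop("blocks overlap", call. = FALSE)
  }
  structure(list(tr = tr, n_volumes = n_volumes, n_sessions = n_sessions,
                 blocks_per_session = blocks_per_session,
                 block_duration = block_duration, block_onsets = block_onsets,
                 trial_duration = trial_duration, trial_gap = trial_gap,
                 trials_per_block = trials_per_block,
                 fixation_s = fixation_s, discard_volumes = discard_volumes,
                 microtime_dt = microtime_dt, input_unit = input_unit,
                 mean_center = mean_center, session_s = session_s),
            class = "stimulus_design")
}

# 0/1 driving input sampled on the microtime grid of one session
session_input <- function(design, session = 1, dt = design$microtime_dt) {
  n_steps <- round(design$session_s / dt)
  t0 <- (seq_len(n_steps) - 1) * dt      # u is held over [t0, t0 + dt)
  u <- numeric(n_steps)
  for (on in design$block_onsets[[session]]) {
    if (design$input_unit == "block") {
      u[t0 >= on - 1e-9 & t0 < on + design$block_duration - 1e-9] <- 1
    } else {
      trial_on <- on + (design$trial_duration + design$trial_gap) *
        (seq_len(design$trials_per_block) - 1)
      for (ton in trial_on)
        u[t0 >= ton - 1e-9 & t0 < ton + design$trial_duration - 1e-9] <- 1
    }
  }
  if (design$mean_center) u <- u - mean(u)
  u
}

# microtime step indices (1-based) at whose end each retained volume is read
session_sample_steps <- function(design, dt = design$microtime_dt) {
  total <- design$n_volumes + design$discard_volumes
  vols <- (design$discard_volumes + 1):total
  round(vols * design$tr / dt)
}

#' Simulate four-region BOLD time series from a parameterized model
#'
#' Integrates the bilinear neuronal model and the Balloon-Windkessel
#' hemodynamics with a fixed-step RK4 scheme on the microtime grid, reads
#' the BOLD observation at volume acquisition times, discards the initial
#' dummy volumes, and optionally adds Gaussian observation noise.
#'
#' @param params a `dcm_params`.
#' @param design a `stimulus_design`.
#' @param noise_sd scalar or per-region observation noise SD (same units as
#'   the BOLD signal).
#' @param seed integer seed used for the noise draws (ignored when
#'   `noise_sd = 0`).
#' @param dt integration step override (defaults to `design$microtime_dt`).
#' @param return_neural also return the sampled neuronal states.
#' @return A `roi_timeseries`: data.frame with columns `time_s`, `session`,
#'   and one column per region; attributes `tr` and `design`. With
#'   `return_neural = TRUE`, the neuronal samples are in attribute `neural`.
#' @export
simulate_timeseries <- function(params, design = stimulus_design(),
                                noise_sd = 0, seed = NULL,
                                dt = design$microtime_dt,
                                return_neural = FALSE) {
  stopifnot(inherits(params, "dcm_params"), inherits(design, "stimulus_design"))
  if (stability_check(params) >= 0)
    stop("unstable parameters: max Re(eigen(A + uB)) >= 0", call. = FALSE)
  noise_sd <- rep_len(noise_sd, 4)
  hemo <- params$hemo
  kap <- vapply(hemo, `[[`, numeric(1), "kappa")
  gam <- vapply(hemo, `[[`, numeric(1), "gamma")
  tau <- vapply(hemo, `[[`, numeric(1), "tau")
  alp <- vapply(hemo, `[[`, numeric(1), "alpha")
  e0  <- vapply(hemo, `[[`, numeric(1), "E0")
  v0  <- hemo[[1]]$V0
  steps <- session_sample_steps(design, dt)
  out <- vector("list", design$n_sessions)
  zs <- vector("list", design$n_sessions)
  for (s in seq_len(design$n_sessions)) {
    u <- session_input(design, s, dt)
    sim <- dcm_integrate_cpp(params$A_vals, params$B_vals, params$C_vals,
                             u, dt, steps, kap, gam, tau, alp, e0, v0)
    out[[s]] <- sim$bold
    zs[[s]] <- sim$z
  }
  y <- do.call(rbind, out)
  colnames(y) <- canonical_region_names
  if (any(noise_sd > 0)) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    for (r in 1:4) y[, r] <- y[, r] + rnorm(nrow(y), 0, noise_sd[r])
  }
  total <- design$n_volumes + design$discard_volumes
  vols <- (design$discard_volumes + 1):total
  time_s <- as.numeric(vapply(seq_len(design$n_sessions), function(s)
    (s - 1) * design$session_s + vols * design$tr, numeric(length(vols))))
  ts <- data.frame(time_s = time_s,
                   session = rep(seq_len(design$n_sessions),
                                 each = design$n_volumes))
  ts <- cbind(ts, as.data.frame(y))
  attr(ts, "tr") <- design$tr
  attr(ts, "design") <- design
  if (return_neural) {
    zmat <- do.call(rbind, zs)
    colnames(zmat) <- canonical_region_names
    attr(ts, "neural") <- zmat
  }
  class(ts) <- c("roi_timeseries", "data.frame")
  ts
}

#' Write / read ROI time series as TSV with a sidecar JSON
#'
#' The TSV holds columns `time_s`, `PrG`, `pSTG`, `mSTG`, `FuG`; session
#' boundaries, TR and (for synthetic data) the hemodynamic constants live in
#' `<path>.json`.
#'
#' @param ts a `roi_timeseries`.
#' @param path TSV file path.
#' @param metadata extra named metadata stored in the sidecar.
#' @export
write_timeseries <- function(ts, path, metadata = list()) {
  df <- as.data.frame(ts)[, c("time_s", canonical_region_names)]
  write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(tr = attr(ts, "tr"),
                 session_lengths = as.integer(table(ts$session))),
            metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("time_s", canonical_region_names)
  if (!identical(colnames(df), need))
    stop("time-series TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar JSON: ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  lens <- as.integer(side$session_lengths)
  if (sum(lens) != nrow(df))
    stop("sidecar session lengths do not match the TSV row count", call. = FALSE)
  df$session <- rep(seq_along(lens), lens)
  df <- df[, c("time_s", "session", canonical_region_names)]
  attr(df, "tr") <- side$tr
  attr(df, "sidecar") <- side
  class(df) <- c("roi_timeseries", "data.frame")
  df
}

#' Write / read a BIDS-style events table
#'
#' Columns `onset`, `duration`, `trial_type` (TSV). One row per block with
#' trial_type "syllable" (the three syllable conditions are modeled as a
#' single grouped input).
#'
#' @param design a `stimulus_design`.
#' @param path file path; for multi-session designs one file per session is
#'   written with suffix `_ses-<k>`.
#' @export
write_events <- function(design, path) {
  stopifnot(inherits(design, "stimulus_design"))
  paths <- character(design$n_sessions)
  for (s in seq_len(design$n_sessions)) {
    df <- data.frame(onset = design$block_onsets[[s]],
                     duration = design$block_duration,
                     trial_type = "syllable")
    p <- if (design$n_sessions == 1) path else
      sub("(\\.[^.]+)?$", sprintf("_ses-%d\\1", s), path)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[s] <- p
  }
  invisible(paths)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.delim(path)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% colnames(df)))
    stop("events TSV must have columns onset, duration, trial_type",
         call. = FALSE)
  bad <- which(df$onset < 0)
  if (length(bad))
    stop("negative onset at row ", bad[1], call. = FALSE)
  df
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
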