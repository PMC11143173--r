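# ROI-level signal conditioning: canonical HRF, block design matrix, DCT
# high-pass filtering, first-eigenvariate extraction with adaptive voxel
# selection, and session concatenation.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak at ~6 s, undershoot
#' peaking at ~16 s, undershoot ratio 1/6), sampled at `dt` over `length_s`
#' seconds and normalized to unit peak.
#'
#' @param dt sampling interval (s).
#' @param length_s kernel support (s).
#' @export
canonical_hrf <- function(dt, length_s = 32) {
  stopifnot(dt > 0)
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Task design matrix for the block paradigm
#'
#' One task regressor (boxcar over the stimulation blocks convolved with the
#' canonical HRF, sampled at the retained volume times), per-session
#' intercepts, and optional motion nuisance columns.
#'
#' @param design a `stimulus_design`.
#' @param nuisance optional matrix/data.frame of nuisance covariates (e.g.
#'   six realignment parameters), with one row per retained volume.
#' @return Matrix with columns `task`, `sess<k>_mean`, and any nuisance
#'   columns.
#' @export
build_design <- function(design, nuisance = NULL) {
  stopifnot(inherits(design, "stimulus_design"))
  dt <- design$microtime_dt
  hrf <- canonical_hrf(dt)
  cols <- lapply(seq_len(design$n_sessions), function(s) {
    box <- numeric(round(design$session_s / dt))
    t0 <- (seq_along(box) - 1) * dt
    for (on in design$block_onsets[[s]])
      box[t0 >= on - 1e-9 & t0 < on + design$block_duration - 1e-9] <- 1
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(box)] * dt
    steps <- session_sample_steps(design, dt)
    conv[steps]
  })
  task <- unlist(cols)
  X <- cbind(task = task, confound_matrix(design))
  colnames(X) <- c("task", paste0("sess", seq_len(design$n_sessions),
                                  "_mean"))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(X))
      stop("nuisance covariates must have one row per retained volume",
           call. = FALSE)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  X
}

# discrete-cosine basis whose components have period > cutoff
dct_basis <- function(T_len, tr, cutoff_s) {
  K <- floor(2 * T_len * tr / cutoff_s)
  if (K < 1) return(NULL)
  t_idx <- seq_len(T_len) - 1
  sapply(seq_len(K), function(k) cos(pi * (2 * t_idx + 1) * k / (2 * T_len)))
}

#' High-pass filter a series by discrete-cosine projection
#'
#' Removes the constant and all DCT components with period longer than
#' `cutoff_s` by orthogonal projection; slow scanner drifts are discarded
#' while faster signal passes unchanged. Idempotent.
#'
#' @param ts numeric vector (one region's series) or matrix (columns =
#'   regions).
#' @param tr sampling interval (s).
#' @param cutoff_s cutoff period (s); must exceed 2 tr. If the series is
#'   shorter than one cutoff period only the constant is removed (with a
#'   warning).
#' @export
dct_highpass <- function(ts, tr, cutoff_s = 128) {
  stopifnot(cutoff_s > 2 * tr)
  M <- as.matrix(ts)
  T_len <- nrow(M)
  X <- cbind(rep(1, T_len), dct_basis(T_len, tr, cutoff_s))
  if (ncol(X) == 1 || T_len * tr < cutoff_s) {
    if (T_len * tr < cutoff_s)
      warning("series shorter than one cutoff period; removing the constant only")
    X <- X[, 1, drop = FALSE]
  }
  Q <- qr.Q(qr(X))
  out <- M - Q %*% crossprod(Q, M)
  if (is.vector(ts)) as.numeric(out) else out
}

#' First eigenvariate of an ROI voxel block
#'
#' Dominant temporal component of the centered voxel-by-time table
#' (leading left singular vector), with the sign chosen so its correlation
#' with the mean voxel series is non-negative and the variance rescaled to
#' the mean voxel variance.
#'
#' @param block T x V matrix (rows = volumes, columns = voxels).
#' @return Length-T numeric summary series.
#' @export
first_eigenvariate <- function(block) {
  X <- as.matrix(block)
  if (ncol(X) < 1 || nrow(X) < 2)
    stop("voxel block needs at least 1 voxel and 2 time points", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12))
    stop("degenerate voxel block: all series constant", call. = FALSE)
  sv <- svd(Xc, nu = 1, nv = 0)
  e <- sv$u[, 1] * sv$d[1]
  mvox <- rowMeans(Xc)
  if (sum(e * mvox) < 0) e <- -e
  target_var <- mean(apply(X, 2, var))
  e * sqrt(target_var / var(e))
}

#' Adaptive voxel-selection threshold
#'
#' Finds the smallest activation threshold on a grid (default 0.10, 0.15,
#' ..., 0.50) at which at least one voxel of the ROI survives
#' (p < threshold). When no voxel survives even at the largest threshold
#' the subject is flagged for exclusion.
#'
#' @param pvals per-voxel activation p-values.
#' @param p0 starting threshold.
#' @param step grid step.
#' @param pmax largest threshold tried.
#' @return List with `selected` (logical mask), `threshold`, and `failed`.
#' @export
adaptive_voxel_selection <- function(pvals, p0 = 0.1, step = 0.05,
                                     pmax = 0.5) {
  stopifnot(all(pvals >= 0), all(pvals <= 1))
  grid <- seq(p0, pmax, by = step)
  for (thr in grid) {
    mask <- pvals < thr
    if (any(mask))
      return(list(selected = mask, threshold = thr, failed = FALSE))
  }
  list(selected = rep(FALSE, length(pvals)), threshold = NA_real_,
       failed = TRUE)
}

#' Concatenate per-session ROI time series
#'
#' Row-wise concatenation of same-region, same-subject sessions; the
#' session index is preserved and per-session means are recorded as
#' confounds.
#'
#' @param sessions list of `roi_ts` objects (see `roi_ts()`).
#' @return A single `roi_ts` spanning all sessions, with attribute
#'   `session_means`.
#' @export
concatenate_sessions <- function(sessions) {
  stopifnot(length(sessions) >= 1)
  ref <- sessions[[1]]
  for (s in sessions[-1]) {
    if (!identical(s$region, ref$region) ||
        !identical(s$subject_id, ref$subject_id))
      stop("sessions belong to different regions or subjects", call. = FALSE)
    if (!isTRUE(all.equal(s$tr, ref$tr)))
      stop("TR mismatch across sessions", call. = FALSE)
  }
  values <- unlist(lapply(sessions, `[[`, "values"))
  session <- rep(seq_along(sessions),
                 vapply(sessions, function(s) length(s$values), integer(1)))
  out <- roi_ts(ref$subject_id, ref$region, values, session, ref$tr)
  attr(out, "session_means") <-
    vapply(sessions, function(s) mean(s$values), numeric(1))
  out
}

#' Single-region time-series container
#'
#' @param subject_id subject label.
#' @param region region label.
#' @param values numeric signal.
#' @param session per-row session index.
#' @param tr repetition time (s).
#' @export
roi_ts <- function(subject_id, region, values, session = 1, tr = 2) {
  stopifnot(all(is.finite(values)))
  session <- rep_len(session, length(values))
  structure(list(subject_id = subject_id, region = region,
                 values = as.numeric(values), session = session, tr = tr),
            class = "roi_ts")
}

#' Extract one region's summary series the way the study pipeline does
#'
#' Applies the adaptive voxel selection to the block's activation p-values,
#' high-pass filters the surviving voxels, and returns their first
#' eigenvariate; `NULL` (exclusion) when no voxel survives.
#'
#' @param block T x V voxel matrix.
#' @param pvals per-voxel activation p-values.
#' @param tr sampling interval (s).
#' @param cutoff_s high-pass cutoff (s).
#' @export
extract_roi_series <- function(block, pvals, tr = 2, cutoff_s = 128) {
  sel <- adaptive_voxel_selection(pvals)
  if (sel$failed) return(NULL)
  kept <- as.matrix(block)[, sel$selected, drop = FALSE]
  filtered <- dct_highpass(kept, tr, cutoff_s)
  first_eigenvariate(filtered)
}
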