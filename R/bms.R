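# Random-effects Bayesian model selection over subjects' log evidences:
# variational Dirichlet scheme, Monte-Carlo exceedance probabilities,
# family-level inference with prior-mass equalization, and Bayesian model
# averaging of coupling parameters.

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a subject-level random variable with
#' Dirichlet-distributed population frequencies. The variational scheme
#' alternates subject responsibilities
#' g_nk proportional to exp(logev_nk + psi(alpha_k) - psi(sum alpha)) with
#' Dirichlet count updates alpha = prior + sum_n g_nk until the counts
#' stabilize.
#'
#' @param log_evidence subjects x models matrix of log evidences (nats).
#' @param prior_counts Dirichlet prior counts (scalar or per model;
#'   default 1).
#' @param mc_samples Monte-Carlo draws for the exceedance probabilities.
#' @param seed seed for the exceedance draws.
#' @param tol convergence tolerance on max |delta alpha|.
#' @return A `bms_result`: Dirichlet counts `alpha`, expected model
#'   frequencies `expected_prob`, `exceedance_prob`, subject
#'   responsibilities `g`, level "model".
#' @export
rfx_bms <- function(log_evidence, prior_counts = 1, mc_samples = 1e6,
                    seed = 1, tol = 1e-4) {
  L <- as.matrix(log_evidence)
  if (!all(is.finite(L))) stop("non-finite log evidences", call. = FALSE)
  K <- ncol(L)
  if (K < 2) stop("need at least 2 models", call. = FALSE)
  n <- nrow(L)
  alpha0 <- rep_len(prior_counts, K)
  alpha <- alpha0
  g <- matrix(1 / K, n, K)
  for (it in seq_len(512)) {
    lg <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  xp <- exceedance_probabilities(alpha, n_samples = mc_samples, seed = seed)
  structure(list(alpha = alpha, expected_prob = alpha / sum(alpha),
                 exceedance_prob = xp, g = g, level = "model",
                 n_subjects = n, mc_samples = mc_samples, seed = seed,
                 model_ids = colnames(L)),
            class = "bms_result")
}

#' Monte-Carlo exceedance probabilities of a Dirichlet distribution
#'
#' Probability, under Dirichlet(`alpha`), that each component has the
#' largest frequency; estimated from seeded gamma draws and normalized so
#' the probabilities sum to exactly 1.
#'
#' @param alpha positive Dirichlet counts.
#' @param n_samples number of draws.
#' @param seed RNG seed (the global RNG state is restored afterwards).
#' @param groups optional factor mapping components to groups; sampled
#'   frequencies are summed within groups before taking the max, giving
#'   group-level (family) exceedance.
#' @export
exceedance_probabilities <- function(alpha, n_samples = 1e6, seed = 1,
                                     groups = NULL) {
  stopifnot(all(alpha > 0))
  K <- length(alpha)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  n_groups <- if (is.null(groups)) K else nlevels(factor(groups))
  wins <- numeric(n_groups)
  chunk <- 1e5
  done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    draws <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    if (!is.null(groups)) {
      gi <- as.integer(factor(groups))
      agg <- matrix(0, m, n_groups)
      for (k in seq_len(K)) agg[, gi[k]] <- agg[, gi[k]] + draws[, k]
      draws <- agg
    }
    best <- max.col(draws, ties.method = "first")
    wins <- wins + tabulate(best, nbins = n_groups)
    done <- done + m
  }
  xp <- wins / sum(wins)
  if (!is.null(groups)) names(xp) <- levels(factor(groups))
  xp
}

#' Family-level random-effects inference
#'
#' Runs `rfx_bms` at the model level with per-model prior counts equalized
#' across families (each model in family f receives
#' max-family-size / |f| prior counts, so every family carries the same
#' prior mass despite the strongly unbalanced family sizes), then computes
#' family exceedance probabilities by summing sampled Dirichlet frequencies
#' within each family before taking the max.
#'
#' @param log_evidence subjects x models matrix; columns must be named with
#'   model ids present in `partition`.
#' @param partition named list family_id -> vector of model ids.
#' @inheritParams rfx_bms
#' @return A `bms_result` with `level = "family"`, plus the underlying
#'   model-level result in `$model_level`.
#' @export
family_level_inference <- function(log_evidence, partition,
                                   mc_samples = 1e6, seed = 1) {
  L <- as.matrix(log_evidence)
  if (is.null(colnames(L)))
    stop("log_evidence must have model-id column names", call. = FALSE)
  sizes <- lengths(partition)
  if (any(sizes == 0)) stop("empty family in partition", call. = FALSE)
  members <- unlist(lapply(partition, as.character), use.names = FALSE)
  if (!setequal(members, colnames(L)))
    stop("partition does not cover the model columns exactly", call. = FALSE)
  fam_of <- rep(names(partition), sizes)
  names(fam_of) <- members
  fam_of <- fam_of[colnames(L)]
  prior <- (max(sizes) / sizes)[fam_of]
  mod <- rfx_bms(L, prior_counts = prior, mc_samples = mc_samples,
                 seed = seed)
  fam_xp <- exceedance_probabilities(mod$alpha, n_samples = mc_samples,
                                     seed = seed, groups = fam_of)
  fam_alpha <- tapply(mod$alpha, fam_of, sum)[names(partition)]
  structure(list(alpha = as.numeric(fam_alpha),
                 expected_prob = as.numeric(fam_alpha / sum(fam_alpha)),
                 exceedance_prob = as.numeric(fam_xp[names(partition)]),
                 level = "family", family_ids = names(partition),
                 n_subjects = nrow(L), mc_samples = mc_samples, seed = seed,
                 model_level = mod),
            class = "bms_result")
}

#' Identify the winning model (or family)
#'
#' Argmax of the exceedance probabilities; exact ties resolve to the lower
#' index with a warning.
#'
#' @param bms a `bms_result`.
#' @return The winning id (model id / family id as stored in the result;
#'   falls back to the index when unnamed).
#' @export
select_winning <- function(bms) {
  stopifnot(inherits(bms, "bms_result"))
  xp <- bms$exceedance_prob
  w <- which(xp == max(xp))
  if (length(w) > 1)
    warning("tied exceedance probabilities; choosing the lower index")
  w <- w[1]
  ids <- if (bms$level == "family") bms$family_ids else bms$model_ids
  if (!is.null(ids)) ids[w] else w
}

#' Bayesian model averaging within a family
#'
#' Averages each subject's posterior-mean coupling matrices across the
#' fitted family members. The default weights follow the family-member
#' model exceedance probabilities (renormalized within the family);
#' `"posterior_frequency"` uses expected model frequencies instead, and
#' `"subject_responsibility"` uses each subject's own model
#' responsibilities g_nk from the Dirichlet scheme. Structurally absent
#' entries contribute 0 to the average.
#'
#' @param fits list (subjects) of lists (family members) of `dcm_fit`
#'   objects; every subject must have a fit for every family member.
#' @param bms the model-level `bms_result` covering the family members
#'   (e.g. `family_level_inference(...)$model_level`).
#' @param family_models character/integer ids of the family members to
#'   average over.
#' @param weighting weight source (see Details).
#' @return List per subject of `bma_params`: averaged `A_vals`, `B_vals`,
#'   `C_vals` and the weights used.
#' @export
bma_within_family <- function(fits, bms,
                              family_models = bms$model_ids,
                              weighting = c("exceedance",
                                            "posterior_frequency",
                                            "subject_responsibility")) {
  weighting <- match.arg(weighting)
  family_models <- as.character(family_models)
  pos <- match(family_models, as.character(bms$model_ids))
  if (anyNA(pos))
    stop("family members missing from the BMS result", call. = FALSE)
  base_w <- switch(weighting,
                   exceedance = bms$exceedance_prob[pos],
                   posterior_frequency = bms$expected_prob[pos],
                   subject_responsibility = NULL)
  lapply(seq_along(fits), function(n) {
    subj_fits <- fits[[n]]
    ids <- vapply(subj_fits, function(f) as.character(f$model_id),
                  character(1))
    miss <- setdiff(family_models, ids)
    if (length(miss))
      stop("subject ", n, " is missing fits for model(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    subj_fits <- subj_fits[match(family_models, ids)]
    w <- if (weighting == "subject_responsibility")
      bms$g[n, pos] else base_w
    if (sum(w) <= 0) w <- rep(1, length(w))
    w <- w / sum(w)
    A <- Reduce(`+`, Map(function(f, wk) wk * f$params$A_vals, subj_fits,
                         w))
    B <- Reduce(`+`, Map(function(f, wk) wk * f$params$B_vals, subj_fits,
                         w))
    C <- Reduce(`+`, Map(function(f, wk) wk * f$params$C_vals, subj_fits,
                         w))
    structure(list(subject_id = subj_fits[[1]]$subject_id,
                   A_vals = A, B_vals = B, C_vals = C,
                   weights = stats::setNames(w, family_models),
                   weighting = weighting),
              class = "bma_params")
  })
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("RFX BMS (%s level, n = %d subjects)\n", x$level, x$n_subjects))
  ids <- if (x$level == "family") x$family_ids else x$model_ids
  if (is.null(ids)) ids <- seq_along(x$exceedance_prob)
  df <- data.frame(id = ids, alpha = round(x$alpha, 3),
                   expected = round(x$expected_prob, 4),
                   exceedance = round(x$exceedance_prob, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
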