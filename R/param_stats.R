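# Group statistics over BMA coupling strengths: covariate residualization,
# per-connection tests, susceptibility correlations, group comparisons, and
# FDR control.

#' Residualize values on demographic covariates
#'
#' Ordinary least squares of `values` on an intercept plus the mean-centered
#' covariates; returns intercept + residuals, i.e. the covariate-adjusted
#' values with the group mean level preserved for the subsequent one-sample
#' tests (pure residuals would have mean zero by construction, making a
#' test of the mean vacuous).
#'
#' @param values per-subject numeric vector.
#' @param covariates data.frame/matrix of covariates (e.g. age, gender,
#'   education), one row per subject.
#' @return Numeric vector of adjusted values (attribute `coefficients`
#'   holds the fitted regression coefficients).
#' @export
residualize <- function(values, covariates) {
  X <- as.data.frame(covariates)
  n <- length(values)
  stopifnot(nrow(X) == n)
  if (n <= ncol(X) + 1)
    stop("need more subjects than covariates", call. = FALSE)
  X <- as.data.frame(lapply(X, function(col) col - mean(col)))
  fit <- stats::lm(values ~ ., data = X)
  alias <- is.na(stats::coef(fit))
  if (any(alias))
    stop("collinear covariate(s): ",
         paste(names(stats::coef(fit))[alias], collapse = ", "),
         call. = FALSE)
  # with centered covariates the intercept is the covariate-adjusted mean,
  # so the adjusted values keep the mean level (shift-invariant)
  adj <- as.numeric(stats::coef(fit)[1] + stats::residuals(fit))
  attr(adj, "coefficients") <- stats::coef(fit)
  adj
}

#' Total task coupling (A + B) on the modulated connections
#'
#' @param A_vals,B_vals 4x4 coupling matrices sharing a structure.
#' @param B_support binary matrix of modulated connections (default: the
#'   nonzero pattern of `B_vals`).
#' @return Matrix of A + B restricted to the modulated connections (zero
#'   elsewhere).
#' @export
coupling_total <- function(A_vals, B_vals, B_support = NULL) {
  A_vals <- as.matrix(A_vals); B_vals <- as.matrix(B_vals)
  if (!all(dim(A_vals) == dim(B_vals)))
    stop("A and B matrices have mismatched dimensions", call. = FALSE)
  if (is.null(B_support)) B_support <- (B_vals != 0) * 1
  (A_vals + B_vals) * (B_support != 0)
}

#' One-sample t test against zero
#'
#' @param values numeric vector (n >= 2, non-degenerate).
#' @return List with `t`, `p` (two-sided, df = n - 1), `mean`, `sd`, `n`.
#' @export
one_sample_test <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  if (sd(values) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  tt <- stats::t.test(values)
  list(t = unname(tt$statistic), p = tt$p.value, mean = mean(values),
       sd = sd(values), n = n)
}

#' Pooled-variance two-sample t test
#'
#' @param g1,g2 numeric vectors (each n >= 2).
#' @param welch use the Welch (unequal-variance) form instead of the
#'   classical pooled form.
#' @return List with `t`, `p`, `df`.
#' @export
two_sample_test <- function(g1, g2, welch = FALSE) {
  if (length(g1) < 2 || length(g2) < 2)
    stop("both groups need at least 2 values", call. = FALSE)
  if (!welch && sd(c(g1 - mean(g1), g2 - mean(g2))) == 0)
    stop("degenerate input: zero pooled variance", call. = FALSE)
  tt <- stats::t.test(g1, g2, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks under ties); the
#' p-value uses the t approximation with df = n - 2, which remains defined
#' under ties.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return List with `r`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  tt <- stats::cor.test(rx, ry, method = "pearson")
  list(r = unname(tt$estimate), p = tt$p.value, n = n)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjustment within the supplied family of p-values.
#'
#' @param pvals p-values in [0, 1].
#' @param q FDR level.
#' @return List with `adjusted` (BH-adjusted p-values) and `rejected`
#'   (flags at level `q`).
#' @export
fdr_adjust <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0), all(pvals <= 1))
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

connection_frame <- function(mats, support, block) {
  idx <- which(support != 0, arr.ind = TRUE)
  rn <- rownames(support)
  do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    vals <- vapply(mats, function(M) M[i, j], numeric(1))
    data.frame(matrix = block, source = rn[j], target = rn[i],
               t(vals))
  }))
}

#' Per-connection group statistics table
#'
#' For every connection of the winning structure, in the endogenous (A),
#' modulatory (B) and total task coupling (A + B, over the modulated
#' connections) blocks: residualize the subject values on the demographic
#' covariates, then compute the all-subject one-sample t test, the Spearman
#' correlation with McGurk susceptibility, per-group one-sample tests, and
#' the between-group two-sample t test. FDR is applied within each
#' statistic family per block (one-sample tests, correlations, per-group
#' tests and group differences each form their own family inside the A, B
#' and A+B blocks).
#'
#' @param bma list of `bma_params` (one per subject, as returned by
#'   `bma_within_family`).
#' @param meta data.frame with columns `subject_id`, `age`, `gender`
#'   (0/1), `education`, `group` ("strong"/"weak").
#' @param susceptibility per-subject susceptibility in the same order.
#' @param q FDR level.
#' @param welch use Welch group tests.
#' @return Data frame with one row per (block, connection): means, SDs,
#'   t/p per test, FDR flags (`q_flag`, `corr_q_flag`, `strong_q_flag`,
#'   `weak_q_flag`, `group_q_flag`).
#' @export
build_stats_table <- function(bma, meta, susceptibility, q = 0.05,
                              welch = FALSE) {
  n <- length(bma)
  if (nrow(meta) != n || length(susceptibility) != n)
    stop("bma, meta and susceptibility must cover the same subjects",
         call. = FALSE)
  A_list <- lapply(bma, `[[`, "A_vals")
  B_list <- lapply(bma, `[[`, "B_vals")
  A_supp <- (Reduce(`+`, lapply(A_list, function(M) M != 0)) > 0) * 1
  diag(A_supp) <- 0
  B_supp <- (Reduce(`+`, lapply(B_list, function(M) M != 0)) > 0) * 1
  AB_list <- Map(function(A, B) coupling_total(A, B, B_supp), A_list, B_list)

  rows <- rbind(connection_frame(A_list, A_supp, "A"),
                connection_frame(B_list, B_supp, "B"),
                connection_frame(AB_list, B_supp, "A+B"))
  val_cols <- grep("^X", colnames(rows))
  covs <- meta[, c("age", "gender", "education")]
  strong <- meta$group == "strong"
  weak <- meta$group == "weak"

  stats_one <- function(v) {
    adj <- residualize(v, covs)
    all_t <- one_sample_test(adj)
    sp <- spearman_corr(adj, susceptibility)
    st <- one_sample_test(adj[strong])
    wk <- one_sample_test(adj[weak])
    gd <- two_sample_test(adj[strong], adj[weak], welch = welch)
    data.frame(mean = all_t$mean, sd = all_t$sd, t = all_t$t, p = all_t$p,
               spearman_r = sp$r, spearman_p = sp$p,
               strong_mean = st$mean, strong_sd = st$sd, strong_t = st$t,
               strong_p = st$p,
               weak_mean = wk$mean, weak_sd = wk$sd, weak_t = wk$t,
               weak_p = wk$p,
               group_t = gd$t, group_p = gd$p)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(rows)), function(k)
    stats_one(as.numeric(rows[k, val_cols]))))
  out <- cbind(rows[, c("matrix", "source", "target")], res)

  # FDR within each statistic family per block (12 A tests, 6 B tests,
  # 6 A+B tests per statistic), mirroring the output table's block layout
  out$q_flag <- out$corr_q_flag <- out$strong_q_flag <- FALSE
  out$weak_q_flag <- out$group_q_flag <- FALSE
  for (blk in unique(out$matrix)) {
    sel <- out$matrix == blk
    out$q_flag[sel] <- fdr_adjust(out$p[sel], q)$rejected
    out$corr_q_flag[sel] <- fdr_adjust(out$spearman_p[sel], q)$rejected
    out$strong_q_flag[sel] <- fdr_adjust(out$strong_p[sel], q)$rejected
    out$weak_q_flag[sel] <- fdr_adjust(out$weak_p[sel], q)$rejected
    out$group_q_flag[sel] <- fdr_adjust(out$group_p[sel], q)$rejected
  }
  rownames(out) <- NULL
  attr(out, "fdr") <- list(method = "BH", q = q,
                           scope = "per statistic family within each block (A / B / A+B)")
  out
}

#' Write the statistics table as CSV plus JSON metadata
#'
#' @param stats table from `build_stats_table`.
#' @param path CSV path (a `.json` twin carries the FDR metadata).
#' @export
write_stats_table <- function(stats, path) {
  write.csv(stats, path, row.names = FALSE)
  jsonlite::write_json(list(fdr = attr(stats, "fdr"),
                            columns = colnames(stats)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
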