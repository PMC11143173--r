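test_that("residualization matches the normal-equations solution and preserves the mean level", {
  set.seed(10)
  n <- 30
  covs <- data.frame(age = rnorm(n, 22, 2), gender = rbinom(n, 1, 0.5),
                     education = rnorm(n, 15, 1.5))
  v <- 0.5 + 0.3 * covs$age + rnorm(n)
  adj <- residualize(v, covs)
  X <- cbind(1, as.matrix(covs))
  beta <- solve(crossprod(X), crossprod(X, v))
  manual <- mean(v) + (v - X %*% beta)   # residuals are centering-invariant
  expect_equal(as.numeric(adj), as.numeric(manual), tolerance = 1e-10)
  # residual component orthogonal to every covariate
  for (k in 1:3)
    expect_lt(abs(cor(adj - mean(adj), covs[[k]])), 1e-10)
  # values exactly linear in a covariate collapse to the intercept
  flat <- residualize(2 * covs$age, covs)
  expect_lt(diff(range(flat)), 1e-10)
  # shifting a covariate by a constant leaves the adjusted t unchanged
  covs2 <- covs; covs2$age <- covs$age + 100
  t1 <- one_sample_test(residualize(v, covs))$t
  t2 <- one_sample_test(residualize(v, covs2))$t
  expect_equal(t1, t2, tolerance = 1e-8)
  covs3 <- covs; covs3$dup <- covs$age
  expect_error(residualize(v, covs3), "collinear")
})

test_that("coupling totals restrict A + B to the modulated connections", {
  A <- matrix(1:16 / 10, 4, 4)
  B <- matrix(0, 4, 4)
  B[2, 1] <- 0.5
  tot <- coupling_total(A, B)
  expect_equal(tot[2, 1], A[2, 1] + 0.5)
  expect_equal(sum(tot != 0), 1)
  expect_true(all(coupling_total(A, matrix(0, 4, 4)) == 0))
  expect_error(coupling_total(A, matrix(0, 3, 3)), "mismatched")
})

test_that("one- and two-sample tests reproduce hand-computed statistics", {
  r <- one_sample_test(c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-abs(r$t), 2), tolerance = 1e-10)
  expect_equal(one_sample_test(c(-2, -1, 1, 2))$t, 0)
  expect_error(one_sample_test(rep(2, 5)), "zero variance")
  g1 <- c(1.1, 2.3, 0.8, 1.9); g2 <- c(2.4, 3.1, 2.8)
  r2 <- two_sample_test(g1, g2)
  sp <- sqrt(((3) * var(g1) + (2) * var(g2)) / 5)
  t_manual <- (mean(g1) - mean(g2)) / (sp * sqrt(1 / 4 + 1 / 3))
  expect_equal(r2$t, t_manual, tolerance = 1e-10)
  expect_equal(r2$df, 5)
  r2s <- two_sample_test(g2, g1)
  expect_equal(r2s$t, -r2$t)
  expect_equal(r2s$p, r2$p)
  expect_equal(two_sample_test(g1, g1)$t, 0)
})

test_that("Spearman correlation uses mid-ranks with the t-approximation", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(spearman_corr(x, sqrt(x))$r, 1)
  expect_equal(spearman_corr(x, -x^3)$r, -1)
  # tied example against the explicit rank formula
  a <- c(1, 2, 2, 4, 5, 5, 7)
  b <- c(3, 1, 4, 4, 6, 8, 9)
  r_manual <- cor(rank(a), rank(b))
  out <- spearman_corr(a, b)
  expect_equal(out$r, r_manual, tolerance = 1e-12)
  expect_equal(out$r, cor(a, b, method = "spearman"), tolerance = 1e-12)
  tstat <- r_manual * sqrt(5 / (1 - r_manual^2))
  expect_equal(out$p, 2 * pt(-abs(tstat), 5), tolerance = 1e-10)
  # invariance under strictly monotone transforms
  expect_equal(spearman_corr(exp(a), b)$r, out$r)
  expect_error(spearman_corr(rep(1, 5), b[1:5]), "constant")
})

test_that("Benjamini-Hochberg flags match the hand step-up and dominate Bonferroni", {
  out <- fdr_adjust(c(0.01, 0.02, 0.2), q = 0.05)
  expect_identical(out$rejected, c(TRUE, TRUE, FALSE))
  expect_equal(out$adjusted, p.adjust(c(0.01, 0.02, 0.2), "BH"))
  expect_false(any(fdr_adjust(rep(0.5, 6))$rejected))
  expect_true(fdr_adjust(0.01)$rejected)
  set.seed(6)
  for (i in 1:20) {
    p <- runif(12)^2
    bh <- fdr_adjust(p, 0.05)$rejected
    bonf <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(bh[bonf]))
  }
})

test_that("stats table detects an injected group gap with the right sign", {
  set.seed(42)
  n <- 12
  rn <- region_cols
  mk_bma <- function(gap) {
    A <- diag(4) * -2
    A[2, 3] <- 0.36 + rnorm(1, 0, 0.15)   # mSTG -> pSTG endogenous
    A[3, 2] <- -0.3 + rnorm(1, 0, 0.15)
    dimnames(A) <- list(rn, rn)
    B <- matrix(0, 4, 4, dimnames = list(rn, rn))
    B["pSTG", "mSTG"] <- gap + rnorm(1, 0, 0.6)
    structure(list(subject_id = "x", A_vals = A, B_vals = B,
                   C_vals = c(0, 0, 0.5, 0.5)), class = "bma_params")
  }
  bma <- c(lapply(1:n, function(i) mk_bma(1.67)),
           lapply(1:n, function(i) mk_bma(0.10)))
  meta <- data.frame(subject_id = paste0("s", 1:(2 * n)),
                     age = rnorm(2 * n, 21, 2),
                     gender = rbinom(2 * n, 1, 0.5),
                     education = rnorm(2 * n, 15, 1.5),
                     group = rep(c("strong", "weak"), each = n))
  susc <- c(runif(n, 0.55, 0.95), runif(n, 0.05, 0.45))
  tab <- build_stats_table(bma, meta, susc)
  row <- tab[tab$matrix == "B" & tab$source == "mSTG" &
               tab$target == "pSTG", ]
  expect_gt(row$group_t, 0)
  expect_lt(row$group_p, 0.01)
  # closure: A+B mean equals A mean + B mean on the same subjects
  for (k in which(tab$matrix == "A+B")) {
    src <- tab$source[k]; tgt <- tab$target[k]
    a_mean <- tab$mean[tab$matrix == "A" & tab$source == src &
                         tab$target == tgt]
    b_mean <- tab$mean[tab$matrix == "B" & tab$source == src &
                         tab$target == tgt]
    expect_equal(tab$mean[k], a_mean + b_mean, tolerance = 1e-10)
  }
})

test_that("a susceptibility-linked coupling yields a positive Spearman row", {
  set.seed(43)
  n <- 20
  rn <- region_cols
  bma <- lapply(1:n, function(i) {
    A <- diag(4) * -2
    A[1, 4] <- rnorm(1, -0.35, 0.2)   # FuG -> PrG
    A[4, 1] <- rnorm(1, -0.3, 0.2)
    dimnames(A) <- list(rn, rn)
    B <- matrix(0, 4, 4, dimnames = list(rn, rn))
    B["PrG", "FuG"] <- rnorm(1, -0.7, 0.4)
    structure(list(subject_id = "x", A_vals = A, B_vals = B,
                   C_vals = c(0, 0, 0.5, 0.5)), class = "bma_params")
  })
  fugprg <- vapply(bma, function(b) b$A_vals["PrG", "FuG"], numeric(1))
  susc <- plogis(2 * scale(fugprg)[, 1] + rnorm(n, 0, 0.2))
  meta <- data.frame(subject_id = paste0("s", 1:n), age = rnorm(n, 21, 2),
                     gender = rbinom(n, 1, 0.5),
                     education = rnorm(n, 15, 1.5),
                     group = rep(c("strong", "weak"), n / 2))
  tab <- build_stats_table(bma, meta, susc)
  row <- tab[tab$matrix == "A" & tab$source == "FuG" & tab$target == "PrG", ]
  expect_gt(row$spearman_r, 0.3)
  expect_lt(row$spearman_p, 0.05)
})
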