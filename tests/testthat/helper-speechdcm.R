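# Shared fixtures: a reduced single-session design for fast inversion tests
# and a mean-coupling parameter set on the winning structure.

small_design <- function(...) {
  stimulus_design(n_volumes = 63, n_sessions = 1, blocks_per_session = 6,
                  ...)
}

the_space <- build_model_space()

mean_params <- function(spec = the_space$models[[13]], self = -2,
                        c_weight = 0.5, zero_b = FALSE) {
  tab <- default_coupling_params()
  rn <- c("PrG", "pSTG", "mSTG", "FuG")
  A <- matrix(0, 4, 4, dimnames = list(rn, rn))
  B <- matrix(0, 4, 4, dimnames = list(rn, rn))
  for (k in seq_len(nrow(tab))) {
    row <- tab[k, ]
    if (row$matrix == "A") A[row$target, row$source] <- row$mean_all
    else B[row$target, row$source] <- row$mean_all
  }
  diag(A) <- self
  A[spec$A == 0 & row(A) != col(A)] <- 0
  B[spec$B == 0] <- 0
  if (zero_b) B[] <- 0
  dcm_params(spec, A, B, c(0, 0, c_weight, c_weight))
}

region_cols <- c("PrG", "pSTG", "mSTG", "FuG")

ts_matrix <- function(ts) as.matrix(as.data.frame(ts)[, region_cols])

mvn_logpdf <- function(y, Cov) {
  n <- length(y)
  ch <- chol(Cov)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, y, transpose = TRUE)^2))
}
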