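test_that("neural drift matches the bilinear form and its fixed points", {
  p <- mean_params()
  expect_equal(neural_drift(rep(0, 4), 0, p), rep(0, 4))
  # at z = 0 the drift under input is the driving column
  expect_equal(neural_drift(rep(0, 4), 1, p), unname(p$C_vals))
  set.seed(4)
  for (i in 1:5) {
    z <- rnorm(4); u <- runif(1)
    manual <- vapply(1:4, function(r)
      sum((p$A_vals[r, ] + u * p$B_vals[r, ]) * z) + p$C_vals[r] * u,
      numeric(1))
    expect_equal(neural_drift(z, u, p), manual, tolerance = 1e-12)
  }
  expect_error(neural_drift(c(NA, 0, 0, 0), 0, p), "non-finite")
})

test_that("hemodynamic drift vanishes at rest and responds to neural input", {
  rest <- list(s = rep(0, 4), f = rep(1, 4), v = rep(1, 4), q = rep(1, 4))
  d <- hemodynamic_drift(rest, rep(0, 4))
  expect_equal(unlist(d), rep(0, 16), ignore_attr = TRUE)
  d2 <- hemodynamic_drift(rest, c(0.3, 0, 0, 0))
  expect_equal(d2$ds[1], 0.3)
  expect_error(hemodynamic_drift(list(s = rep(0, 4), f = rep(-1, 4),
                                      v = rep(1, 4), q = rep(1, 4)),
                                 rep(0, 4)), "positive")
})

test_that("BOLD observation is zero at rest and increases as deoxyhemoglobin drops", {
  expect_equal(bold_observation(1, 1), 0)
  expect_gt(bold_observation(1, 0.9), 0)
  hemo <- hemodynamic_params()
  for (v in c(0.9, 1, 1.1)) for (q in c(0.8, 1, 1.2)) {
    k1 <- 7 * hemo$E0; k3 <- 2 * hemo$E0 - 0.2
    manual <- hemo$V0 * (k1 * (1 - q) + 2 * (1 - q / v) + k3 * (1 - v))
    expect_equal(bold_observation(v, q, hemo), manual)
  }
})

test_that("stability check returns the worst-case spectral abscissa", {
  expect_equal(stability_check(-diag(4)), -1)
  A <- -diag(4); A[1, 1] <- 0.1
  expect_equal(stability_check(A), 0.1)
  set.seed(9)
  M <- matrix(rnorm(16), 4)
  expect_equal(stability_check(M),
               max(Re(eigen(M)$values)), tolerance = 1e-12)
})

test_that("zero input produces an identically zero signal; defaults give 567 volumes", {
  spec <- the_space$models[[13]]
  p <- mean_params()
  p0 <- dcm_params(spec, p$A_vals, p$B_vals, c(0, 0, 0, 0))
  ts <- simulate_timeseries(p0, small_design())
  expect_true(all(ts_matrix(ts) == 0))
  ts_full <- simulate_timeseries(p, dt = 0.5)
  expect_equal(nrow(ts_full), 567)
  expect_equal(unname(table(ts_full$session)), rep(189L, 3),
               ignore_attr = TRUE)
})

test_that("simulation is deterministic given a seed and refuses unstable parameters", {
  p <- mean_params()
  d <- small_design()
  a <- simulate_timeseries(p, d, noise_sd = 0.001, seed = 7)
  b <- simulate_timeseries(p, d, noise_sd = 0.001, seed = 7)
  expect_identical(a, b)
  bad <- p
  bad$A_vals[1, 1] <- 0.2
  expect_error(simulate_timeseries(bad, d), "unstable")
})

test_that("halving the integration step changes the BOLD by < 1e-3 RMS", {
  p <- mean_params()
  d <- small_design()
  y1 <- ts_matrix(simulate_timeseries(p, d, dt = d$tr / 16))
  y2 <- ts_matrix(simulate_timeseries(p, d, dt = d$tr / 32))
  expect_lt(sqrt(mean((y1 - y2)^2)) / sd(y1), 1e-3)
})

test_that("neural superposition holds exactly when B = 0", {
  spec <- the_space$models[[13]]
  p <- mean_params(zero_b = TRUE)
  d <- small_design()
  z1 <- attr(simulate_timeseries(p, d, return_neural = TRUE), "neural")
  p2 <- dcm_params(spec, p$A_vals, p$B_vals, 2 * p$C_vals)
  z2 <- attr(simulate_timeseries(p2, d, return_neural = TRUE), "neural")
  expect_equal(z2, 2 * z1, tolerance = 1e-9)
})

test_that("linear-limit neural trajectory matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  p <- mean_params(zero_b = TRUE)
  d <- stimulus_design(tr = 1, n_volumes = 40, n_sessions = 1,
                       blocks_per_session = 1, block_duration = 3,
                       block_onsets = list(5), trial_duration = 3,
                       trial_gap = 0, trials_per_block = 1,
                       fixation_s = 0, discard_volumes = 0,
                       microtime_dt = 0.05)
  z_sim <- attr(simulate_timeseries(p, d, return_neural = TRUE), "neural")
  A <- p$A_vals
  Cu <- unname(p$C_vals)
  prop <- function(z, dt, u) {
    E <- as.matrix(Matrix::expm(A * dt))
    as.numeric(E %*% z + solve(A, (E - diag(4)) %*% (Cu * u)))
  }
  z <- rep(0, 4)
  z_ref <- matrix(0, 40, 4)
  breaks <- c(0, 5, 8, 40)   # u = 0, 1, 0
  uvals <- c(0, 1, 0)
  t_now <- 0
  for (k in 1:40) {
    t_next <- k
    while (t_now < t_next - 1e-12) {
      seg_end <- min(t_next, breaks[findInterval(t_now + 1e-9, breaks) + 1])
      u <- uvals[findInterval(t_now + 1e-9, breaks)]
      z <- prop(z, seg_end - t_now, u)
      t_now <- seg_end
    }
    z_ref[k, ] <- z
  }
  expect_lt(max(abs(z_sim - z_ref)), 1e-3)
})

test_that("compiled trajectory agrees with an independent stiff-solver integration", {
  skip_if_not_installed("deSolve")
  p <- mean_params()
  d <- stimulus_design(tr = 2, n_volumes = 30, n_sessions = 1,
                       blocks_per_session = 2, block_duration = 21,
                       fixation_s = 20, discard_volumes = 5,
                       block_onsets = list(c(20, 41)))
  sim <- simulate_timeseries(p, d, return_neural = TRUE)
  u_fun <- local({
    dt <- d$microtime_dt
    u <- speechdcm:::session_input(d, 1, dt)
    stats::approxfun((seq_along(u) - 1) * dt, u, method = "constant",
                     rule = 2)
  })
  hemo <- hemodynamic_params()
  rhs <- function(t, y, parms) {
    z <- y[1:4]; s <- y[5:8]; f <- y[9:12]; v <- y[13:16]; q <- y[17:20]
    u <- u_fun(t)
    dz <- neural_drift(z, u, p)
    dh <- hemodynamic_drift(list(s = s, f = f, v = v, q = q), z, hemo)
    list(c(dz, dh$ds, dh$df, dh$dv, dh$dq))
  }
  y0 <- c(rep(0, 8), rep(1, 12))
  times <- c(0, sim$time_s)
  ref <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-9, atol = 1e-10)
  bold_ref <- sapply(1:4, function(r)
    bold_observation(ref[-1, 13 + r], ref[-1, 17 + r], hemo))
  expect_lt(max(abs(ts_matrix(sim) - bold_ref)) / max(abs(bold_ref)), 1e-4)
})

test_that("a single-region impulse response peaks 3-7 s after stimulation", {
  spec <- the_space$models[[13]]
  A <- diag(4) * -1
  B <- matrix(0, 4, 4)
  p <- dcm_params(spec, A, B, c(0, 0, 1, 0))
  d <- stimulus_design(tr = 1, n_volumes = 30, n_sessions = 1,
                       blocks_per_session = 1, block_duration = 2,
                       block_onsets = list(0), trial_duration = 2,
                       trial_gap = 0, trials_per_block = 1, fixation_s = 0,
                       discard_volumes = 0, microtime_dt = 0.0625)
  y <- ts_matrix(simulate_timeseries(p, d))[, "mSTG"]
  t_peak <- which.max(y) * d$tr
  expect_gte(t_peak, 3)
  expect_lte(t_peak, 7)
})

test_that("time series and events tables survive a disk round trip", {
  p <- mean_params()
  d <- small_design()
  ts <- simulate_timeseries(p, d, noise_sd = 1e-4, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_timeseries(ts, path)
  back <- read_timeseries(path)
  expect_equal(ts_matrix(back), ts_matrix(ts), tolerance = 1e-10)
  expect_equal(back$session, ts$session)
  ev_path <- tempfile(fileext = ".tsv")
  write_events(d, ev_path)
  ev <- read_events(ev_path)
  expect_equal(nrow(ev), 6)
  expect_equal(ev$duration, rep(21, 6))
  bad <- ev; bad$onset[2] <- -1
  bad_path <- tempfile(fileext = ".tsv")
  write.table(bad, bad_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(bad_path), "row 2")
})

test_that("dcm_params enforces the structural zero pattern and self-inhibition", {
  spec <- the_space$models[[37]]  # family 5: no PrG-mSTG endogenous link
  A <- diag(4) * -1
  A[3, 1] <- 0.5  # mSTG <- PrG not in structure
  expect_error(dcm_params(spec, A, matrix(0, 4, 4), c(0, 0, 0.5, 0.5)),
               "outside the model structure")
  A2 <- diag(4) * -1; A2[1, 1] <- 0
  expect_error(dcm_params(spec, A2, matrix(0, 4, 4), c(0, 0, 0.5, 0.5)),
               "negative")
})
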