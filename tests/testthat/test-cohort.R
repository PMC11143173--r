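test_that("default ground truth yields 45 stable group-structured subjects", {
  truth <- generate_ground_truth(seed = 2)
  expect_length(truth, 45)
  expect_equal(sum(vapply(truth, `[[`, character(1), "group") == "strong"),
               25)
  for (su in truth[c(1, 20, 40)]) {
    expect_lt(stability_check(su$params), 0)
    expect_true(all(diag(su$params$A_vals) < 0))
  }
  # group consistency of behavioral targets
  tgt <- vapply(truth, `[[`, numeric(1), "susceptibility_target")
  grp <- vapply(truth, `[[`, character(1), "group")
  expect_true(all(tgt[grp == "strong"] > 0.5))
  expect_true(all(tgt[grp == "weak"] < 0.5))
})

test_that("zero-SD coupling distributions reproduce the group means exactly", {
  cfg <- cohort_config(n_strong = 2, n_weak = 2)
  cfg$coupling$sd_strong[] <- 0
  cfg$coupling$sd_weak[] <- 0
  truth <- generate_ground_truth(cfg, seed = 3)
  expect_equal(truth[[1]]$params$A_vals, truth[[2]]$params$A_vals)
  row <- cfg$coupling[cfg$coupling$matrix == "B" &
                        cfg$coupling$source == "mSTG" &
                        cfg$coupling$target == "pSTG", ]
  expect_equal(truth[[1]]$params$B_vals["pSTG", "mSTG"], row$mean_strong)
  expect_equal(truth[[3]]$params$B_vals["pSTG", "mSTG"], row$mean_weak)
})

test_that("generated coupling draws concentrate on the configured means", {
  cfg <- cohort_config(n_strong = 500, n_weak = 2)
  truth <- generate_ground_truth(cfg, seed = 4)
  strong <- Filter(function(s) s$group == "strong", truth)
  vals <- vapply(strong, function(s) s$params$A_vals["pSTG", "PrG"],
                 numeric(1))
  row <- cfg$coupling[cfg$coupling$matrix == "A" &
                        cfg$coupling$source == "PrG" &
                        cfg$coupling$target == "pSTG", ]
  # stability rejection can perturb the margins slightly; 3 SE band
  expect_lt(abs(mean(vals) - row$mean_strong),
            3 * row$sd_strong / sqrt(length(vals)) + 0.02)
})

test_that("behavioral trials realize the target susceptibility curve", {
  tb <- generate_behavioral_trials(0.7, "s1", seed = 6)
  expect_equal(nrow(tb), 290)
  tb0 <- generate_behavioral_trials(0, "s1", seed = 6)
  expect_equal(sum(tb0$response == "ta"), 0)
  # deterministic mode peaks at +133 (argmax set contains the peak SOA)
  for (tgt in c(0.3, 0.55, 0.7, 0.95)) {
    det <- generate_behavioral_trials(tgt, "s1", sample = FALSE)
    rc <- response_curve(det, "s1")
    expect_true(133 %in% rc$soa_ms[rc$ta == max(rc$ta)])
    expect_equal(susceptibility(det, "s1"), round(10 * tgt) / 10)
  }
  # binomial mode is unbiased at the peak
  svals <- vapply(1:300, function(i)
    susceptibility(generate_behavioral_trials(0.7, "s1", seed = 1000 + i),
                   "s1"), numeric(1))
  expect_lt(abs(mean(svals) - 0.7), 0.03)
})

test_that("cohorts are reproducible from the seed and carry consistent metadata", {
  cfg <- cohort_config(n_strong = 2, n_weak = 2, design = small_design())
  c1 <- generate_cohort(cfg, seed = 9)
  c2 <- generate_cohort(cfg, seed = 9)
  expect_identical(ts_matrix(c1$subjects[[1]]$ts),
                   ts_matrix(c2$subjects[[1]]$ts))
  expect_identical(c1$subjects[[3]]$trials, c2$subjects[[3]]$trials)
  expect_identical(c1$subjects[[2]]$meta, c2$subjects[[2]]$meta)
  c3 <- generate_cohort(cfg, seed = 10)
  expect_false(identical(ts_matrix(c1$subjects[[1]]$ts),
                         ts_matrix(c3$subjects[[1]]$ts)))
  for (su in c1$subjects) {
    expect_equal(nrow(su$ts), 63)
    expect_true(su$meta$age >= 18 && su$meta$age <= 28)
    expect_true(su$meta$gender %in% 0:1)
  }
})

test_that("the observation-noise scale follows the configured SNR", {
  d <- small_design()
  cfg <- cohort_config(n_strong = 2, n_weak = 2, design = d, snr = 2)
  coh <- generate_cohort(cfg, seed = 5)
  su <- coh$subjects[[1]]
  clean <- simulate_timeseries(su$params, d, noise_sd = 0)
  Q <- qr.Q(qr(speechdcm:::confound_matrix(d)))
  Yc <- ts_matrix(clean) - Q %*% crossprod(Q, ts_matrix(clean))
  expect_equal(unname(attr(su$ts, "noise_sd")),
               unname(apply(Yc, 2, sd) / 2), tolerance = 1e-10)
})

test_that("downstream recovery improves with SNR", {
  d <- small_design()
  spec <- the_space$models[[13]]
  r_at <- function(snr) {
    coh <- generate_cohort(cohort_config(n_strong = 2, n_weak = 2,
                                         design = d, snr = snr), seed = 21)
    tv <- ev <- c()
    for (su in coh$subjects) {
      fit <- fit_model(su$ts, spec, d)
      m <- spec$A == 1 & row(spec$A) != col(spec$A)
      tv <- c(tv, su$params$A_vals[m] + su$params$B_vals[m])
      ev <- c(ev, fit$params$A_vals[m] + fit$params$B_vals[m])
    }
    cor(tv, ev)
  }
  expect_gt(r_at(8), r_at(0.25))
})

test_that("cohort datasets round-trip through the on-disk layout", {
  cfg <- cohort_config(n_strong = 2, n_weak = 2, design = small_design())
  coh <- generate_cohort(cfg, seed = 13)
  dir <- tempfile()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_cohort_data(dir)
  expect_equal(nrow(back$meta), 4)
  expect_length(back$ts, 4)
  expect_equal(ts_matrix(back$ts[["sub-01"]]),
               ts_matrix(coh$subjects[[1]]$ts), tolerance = 1e-9)
  expect_equal(susceptibility(back$trials, "sub-02"),
               susceptibility(coh$subjects[[2]]$trials, "sub-02"))
})
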