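test_that("simulated observations are prediction plus Gaussian noise", {
  par <- case_params()
  pA <- built_in_profile("A")
  d <- uniform_design(10, 60)
  # zero noise reproduces the prediction exactly
  ds0 <- simulate_observations(d, pA, par, sigma = 0, n_reps = 3, seed = 1)
  pred <- predict_logN(pA, par, as.numeric(d))
  expect_equal(ds0$observations, matrix(pred, 10, 3))
  # the same seed reproduces the same dataset
  a <- simulate_observations(d, pA, par, seed = 99)
  b <- simulate_observations(d, pA, par, seed = 99)
  expect_identical(a$observations, b$observations)
  # moments of a large draw at a single time point
  big <- simulate_observations(sampling_design(30), pA, par, sigma = 0.25,
                               n_reps = 1e4, seed = 5)
  mu <- predict_logN(pA, par, 30)
  expect_lt(abs(mean(big$observations) - mu), 3 * 0.25 / sqrt(1e4) * 10)
  expect_lt(abs(sd(big$observations) - 0.25) / 0.25, 0.05)
})

test_that("noiseless data returns the generating parameters", {
  par <- case_params()
  for (p in all_profiles()) {
    d <- uniform_design(8, profile_duration(p))
    ds <- simulate_observations(d, p, par, sigma = 0, n_reps = 1)
    # two-parameter fit, logN0 known
    f2 <- fit_bigelow(ds, p, c(3, 5), list(T_ref = 57.5, logN0 = 8))
    expect_true(f2$converged)
    expect_equal(unname(f2$estimates["D_ref"]), 3.9, tolerance = 1e-4)
    expect_equal(unname(f2$estimates["z"]), 4.2, tolerance = 1e-4)
    # three-parameter fit recovers the initial count too
    f3 <- fit_bigelow(ds, p, c(3, 5, 7), list(T_ref = 57.5))
    expect_true(f3$converged)
    expect_equal(unname(f3$estimates), c(3.9, 4.2, 8), tolerance = 1e-4)
  }
})

test_that("duplicating a dataset shrinks standard errors by the df-corrected factor", {
  par <- case_params()
  pA <- built_in_profile("A")
  d <- uniform_design(10, 60)
  ds <- simulate_observations(d, pA, par, sigma = 0.25, n_reps = 1, seed = 3)
  dup <- list(times = c(ds$times, ds$times),
              observations = rbind(ds$observations, ds$observations))
  fx <- list(T_ref = 57.5, logN0 = 8)
  f1 <- fit_bigelow(ds, pA, c(3.9, 4.2), fx)
  f2 <- fit_bigelow(dup, pA, c(3.9, 4.2), fx)
  expect_equal(f2$estimates, f1$estimates, tolerance = 1e-6)
  # cov scales as s2_new (J'J_new)^-1 = [2*SSE/(2N-2)] * (2 J'J)^-1
  N <- length(ds$times)
  expected_ratio <- sqrt((N - 2) / (2 * N - 2))
  expect_equal(unname(f2$se / f1$se), rep(expected_ratio, 2),
               tolerance = 1e-6)
})

test_that("degenerate datasets are flagged non-converged, not raised", {
  par <- case_params()
  pA <- built_in_profile("A")
  one <- simulate_observations(sampling_design(30), pA, par, n_reps = 3,
                               seed = 2)
  f <- fit_bigelow(one, pA, c(3, 5), list(T_ref = 57.5))
  expect_false(f$converged)
  expect_true(all(is.na(f$se)))
  # one point, one replicate: too few observations for any fit
  tiny <- simulate_observations(sampling_design(30), pA, par, n_reps = 1,
                                seed = 2)
  expect_false(fit_bigelow(tiny, pA, c(3, 5), list(T_ref = 57.5))$converged)
})

test_that("Monte Carlo precision runs are seed-reproducible", {
  par <- case_params()
  pA <- built_in_profile("A")
  d <- uniform_design(6, 60)
  m1 <- monte_carlo_precision(d, pA, par, n_sims = 10, seed = 8)
  m2 <- monte_carlo_precision(d, pA, par, n_sims = 10, seed = 8)
  expect_identical(m1$results, m2$results)
  expect_equal(m1$fraction_precise, m2$fraction_precise)
  expect_true(all(m1$fraction_precise >= 0 & m1$fraction_precise <= 1))
})

test_that("mean per-fit standard errors track the Cramer-Rao prediction", {
  # with logN0 known, the asymptotic covariance is sigma^2 (3 F_raw)^-1
  # for 3 replicates; the Monte Carlo mean per-fit SE should sit near it
  par <- case_params()
  pA <- built_in_profile("A")
  d <- uniform_design(10, 60)
  sigma <- 0.25
  mc <- monte_carlo_precision(d, pA, par, sigma = sigma, n_reps = 3,
                              n_sims = 50, seed = 12, fit_logN0 = FALSE)
  F_raw <- fim(d, pA, par, scaled = FALSE)
  cr <- sigma * sqrt(diag(solve(3 * F_raw)))
  expect_equal(unname(mc$mean_se["D_ref"]), unname(cr["D_ref"]),
               tolerance = 0.25)
  expect_equal(unname(mc$mean_se["z"]), unname(cr["z"]),
               tolerance = 0.25)
})

test_that("halving the noise roughly halves the standard errors", {
  par <- case_params()
  pA <- built_in_profile("A")
  d <- uniform_design(10, 60)
  hi <- monte_carlo_precision(d, pA, par, sigma = 0.25, n_sims = 50,
                              seed = 14)
  lo <- monte_carlo_precision(d, pA, par, sigma = 0.125, n_sims = 50,
                              seed = 14)
  for (p in c("D_ref", "z")) {
    ratio <- unname(hi$mean_se[p] / lo$mean_se[p])
    expect_gt(ratio, 2 * 0.8)
    expect_lt(ratio, 2 * 1.2)
  }
})

test_that("Monte Carlo estimates are centred on the generating parameters", {
  par <- case_params()
  pA <- built_in_profile("A")
  # identifiable cells: uniform design with the default fit, and the
  # optimized design with logN0 known
  mc_u <- monte_carlo_precision(uniform_design(10, 60), pA, par,
                                n_sims = 100, seed = 16)
  conv <- mc_u$results[mc_u$results$converged, ]
  for (p in c("D_hat", "z_hat")) {
    truth <- if (p == "D_hat") 3.9 else 4.2
    sem <- sd(conv[[p]]) / sqrt(nrow(conv))
    expect_lt(abs(mean(conv[[p]]) - truth), 2 * sem + 0.02)
  }
  oed <- optimize_design(pA, par, 10, seed = 17)
  mc_o <- monte_carlo_precision(oed$design, pA, par, n_sims = 100,
                                seed = 18, fit_logN0 = FALSE)
  conv_o <- mc_o$results[mc_o$results$converged, ]
  expect_lt(abs(mean(conv_o$D_hat) - 3.9),
            2 * sd(conv_o$D_hat) / sqrt(nrow(conv_o)) + 0.02)
  expect_lt(abs(mean(conv_o$z_hat) - 4.2),
            2 * sd(conv_o$z_hat) / sqrt(nrow(conv_o)) + 0.02)
})
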