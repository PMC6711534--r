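test_that("rate integral is exact on isothermal and reference cases", {
  par <- case_params()
  iso_ref <- isothermal_profile(57.5)
  # at T = T_ref the rate is 1 per minute
  expect_equal(log_reduction_integral(iso_ref, par, 1), 1)
  expect_equal(log_reduction_integral(iso_ref, par, 7.3), 7.3)
  # one D-value at the reference temperature loses one log
  expect_equal(predict_logN(iso_ref, par, 3.9), 8 - 1)
  expect_equal(predict_logN(iso_ref, par, 0), 8)
  # huge z: temperature dependence switched off, I(t) -> t
  par_flat <- bigelow_params(3.9, 1e9, 57.5, 8)
  expect_equal(log_reduction_integral(built_in_profile("A"), par_flat, 37),
               37, tolerance = 1e-6)
})

test_that("profile A accumulates 14.365 reference-minutes over the full treatment", {
  # frozen from the closed form; independently confirmed by adaptive
  # quadrature of the rate integrand (rel. difference < 1e-12)
  par <- case_params()
  pA <- built_in_profile("A")
  expect_equal(log_reduction_integral(pA, par, 60), 14.36486872,
               tolerance = 1e-7)
  expect_equal(predict_logN(pA, par, 60), 4.31670033, tolerance = 1e-7)
})

test_that("closed-form integrals agree with adaptive quadrature", {
  par <- case_params()
  set.seed(21)
  for (p in all_profiles()) {
    times <- runif(50, 1e-3, profile_duration(p))
    I_closed <- log_reduction_integral(p, par, times)
    I_quad <- vapply(times, function(t) quad_I(p, par, t), numeric(1))
    expect_equal(I_closed, I_quad, tolerance = 1e-8)
    sz_closed <- local_sensitivities(p, par, times)$sens_z
    sz_quad <- vapply(times, function(t) quad_sens_z(p, par, t), numeric(1))
    expect_equal(sz_closed, sz_quad, tolerance = 1e-8)
  }
})

test_that("logN is non-increasing in time on every profile", {
  par <- case_params()
  for (p in all_profiles()) {
    grid <- seq(0, profile_duration(p), length.out = 200)
    expect_true(all(diff(predict_logN(p, par, grid)) <= 1e-12))
  }
})

test_that("sensitivities vanish at t = 0 and satisfy the D-identity", {
  par <- case_params()
  for (p in all_profiles()) {
    s0 <- local_sensitivities(p, par, 0)
    expect_equal(s0$sens_D, 0)
    expect_equal(s0$sens_z, 0)
    times <- seq(0, profile_duration(p), length.out = 25)
    s <- local_sensitivities(p, par, times)
    # sens_D = (logN0 - logN)/D_ref, an algebraic identity of the model
    expect_equal(s$sens_D,
                 (par$logN0 - predict_logN(p, par, times)) / par$D_ref,
                 tolerance = 1e-12)
    # sens_D = I/D^2 >= 0 and non-decreasing
    expect_true(all(s$sens_D >= 0))
    expect_true(all(diff(s$sens_D) >= -1e-12))
  }
})

test_that("analytic and finite-difference sensitivities agree", {
  par <- case_params()
  set.seed(31)
  for (p in all_profiles()) {
    times <- runif(50, 0.05 * profile_duration(p), profile_duration(p))
    sa <- local_sensitivities(p, par, times, method = "analytic")
    sf <- local_sensitivities(p, par, times, method = "fd")
    expect_equal(sa$sens_D, sf$sens_D, tolerance = 1e-4)
    expect_equal(sa$sens_z, sf$sens_z, tolerance = 1e-4)
  }
})

test_that("sensitivity landmarks sit where the profiles place them", {
  par <- case_params()
  pA <- built_in_profile("A")
  grid <- seq(0, 60, by = 0.1)
  szA <- local_sensitivities(pA, par, grid)$sens_z
  t_min_z <- grid[which.min(szA)]
  expect_gte(t_min_z, 54)
  expect_lte(t_min_z, 58)
  # both |sensitivities| peak at the end of the treatment
  sA <- local_sensitivities(pA, par, grid)
  expect_equal(grid[which.max(abs(sA$sens_D))], 60)
  expect_equal(grid[which.max(abs(sA$sens_z))], 60)

  pB <- built_in_profile("B")
  szB <- scaled_sensitivities(pB, par, grid)$sens_z
  t_min_B <- grid[which.min(szB)]
  t_max_B <- grid[which.max(szB)]
  expect_gte(t_min_B, 26); expect_lte(t_min_B, 30)
  expect_gte(t_max_B, 30); expect_lte(t_max_B, 34)
})

test_that("parameter scaling preserves extrema locations", {
  par <- case_params()
  p <- built_in_profile("B")
  grid <- seq(0, 60, by = 0.25)
  raw <- local_sensitivities(p, par, grid)
  sc <- scaled_sensitivities(p, par, grid)
  expect_equal(sc$sens_D, par$D_ref * raw$sens_D)
  expect_equal(sc$sens_z, par$z * raw$sens_z)
  expect_equal(which.min(sc$sens_z), which.min(raw$sens_z))
  expect_equal(which.max(sc$sens_z), which.max(raw$sens_z))
  s0 <- scaled_sensitivities(p, par, 0)
  expect_equal(unlist(s0), c(sens_D = 0, sens_z = 0))
})

test_that("prediction table has the export layout and domain errors propagate", {
  par <- case_params()
  pA <- built_in_profile("A")
  tab <- survival_prediction(pA, par, c(0, 30, 60))
  expect_named(tab, c("time_min", "logN", "sens_D", "sens_z"))
  expect_equal(tab$logN[1], 8)
  expect_error(predict_logN(pA, par, 61), "outside")
  expect_error(local_sensitivities(pA, par, -1), "outside")
})
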