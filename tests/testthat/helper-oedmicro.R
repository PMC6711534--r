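# Shared fixtures: case-study kinetics and quadrature oracles.

case_params <- function() bigelow_params(3.9, 4.2, 57.5, 8)

all_profiles <- function() {
  list(A = built_in_profile("A"), B = built_in_profile("B"),
       C = built_in_profile("C"))
}

# constant-temperature profile, for isothermal sanity checks
isothermal_profile <- function(temp, duration = 10) {
  temperature_profile(c(0, duration), c(temp, temp),
                      sprintf("iso%g", temp))
}

# Independent numerical oracle for the rate integral
# I(t) = int_0^t 10^((T - T_ref)/z) dtau
quad_I <- function(profile, params, t) {
  f <- function(tau) {
    10^((temperature_at(profile, tau) - params$T_ref) / params$z)
  }
  stats::integrate(f, 0, t, rel.tol = 1e-11, subdivisions = 500L)$value
}

# Independent oracle for the z-sensitivity:
# (ln10 / (D z^2)) * int_0^t (T - T_ref) 10^((T - T_ref)/z) dtau
quad_sens_z <- function(profile, params, t) {
  g <- function(tau) {
    u <- temperature_at(profile, tau) - params$T_ref
    u * 10^(u / params$z)
  }
  J <- stats::integrate(g, 0, t, rel.tol = 1e-11, subdivisions = 500L)$value
  log(10) / (params$D_ref * params$z^2) * J
}
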