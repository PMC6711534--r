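#' Bigelow model parameters
#'
#' Kinetic parameter vector for first-order (log-linear) thermal
#' inactivation with D-value temperature dependence
#' `D(T) = D_ref * 10^(-(T - T_ref)/z)`: the D-value drops ten-fold for
#' every `z` degrees above the reference temperature. Under a dynamic
#' profile `T(t)` the log count follows
#' `dlogN/dt = -(1/D_ref) * 10^((T(t) - T_ref)/z)`.
#'
#' @param D_ref D-value at the reference temperature (min, > 0).
#' @param z z-value (degC, > 0): temperature increase for a ten-fold
#'   reduction of the D-value.
#' @param T_ref Reference temperature (degC).
#' @param logN0 Initial count (log10 CFU/ml).
#' @return An object of class `bigelow_params`.
#' @export
#' @examples
#' bigelow_params() # case-study values for L. monocytogenes
bigelow_params <- function(D_ref = 3.9, z = 4.2, T_ref = 57.5, logN0 = 8) {
  vals <- c(D_ref = D_ref, z = z, T_ref = T_ref, logN0 = logN0)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("all Bigelow parameters must be finite", call. = FALSE)
  }
  if (D_ref <= 0) stop("D_ref must be > 0", call. = FALSE)
  if (z <= 0) stop("z must be > 0", call. = FALSE)
  structure(as.list(vals), class = "bigelow_params")
}

#' @export
print.bigelow_params <- function(x, ...) {
  cat(sprintf(
    "Bigelow parameters: D_%.4g = %g min, z = %g degC, logN0 = %g log10 CFU/ml\n",
    x$T_ref, x$D_ref, x$z, x$logN0))
  invisible(x)
}

# Segment decomposition of a piecewise-linear profile.
.profile_segments <- function(profile) {
  tt <- profile$anchor_times
  TT <- profile$anchor_temps
  ns <- length(tt) - 1L
  list(t0 = tt[-(ns + 1L)], T0 = TT[-(ns + 1L)],
       beta = diff(TT) / diff(tt), dt = diff(tt), anchor_times = tt)
}

# Closed-form per-segment integrals of the Bigelow rate.
#
# With k = ln(10)/z and u(s) = T0 - T_ref + beta*s on a segment:
#   I  = int exp(k*u) ds            (the lethality-like rate integral)
#   J  = int u * exp(k*u) ds        (inner integral of the z-sensitivity)
# Both are exact for linear T(s); the beta = 0 branches are the limits.
.seg_I <- function(u0, beta, k, s) {
  ifelse(abs(beta) < .Machine$double.eps,
         exp(k * u0) * s,
         exp(k * u0) * expm1(k * beta * s) / (k * beta))
}

.seg_J <- function(u0, beta, k, s) {
  u1 <- u0 + beta * s
  ifelse(abs(beta) < .Machine$double.eps,
         u0 * exp(k * u0) * s,
         (exp(k * u1) * (u1 - 1 / k) - exp(k * u0) * (u0 - 1 / k)) / (beta * k))
}

# I(t) and J(t) at arbitrary times, via cumulative anchor values plus a
# partial segment. Vectorized over t; t must already be in-domain.
.kinetic_integrals <- function(profile, params, t) {
  seg <- .profile_segments(profile)
  k <- log(10) / params$z
  u0 <- seg$T0 - params$T_ref
  cumI <- c(0, cumsum(.seg_I(u0, seg$beta, k, seg$dt)))
  cumJ <- c(0, cumsum(.seg_J(u0, seg$beta, k, seg$dt)))
  j <- findInterval(t, seg$anchor_times, rightmost.closed = TRUE,
                    all.inside = TRUE)
  ds <- t - seg$t0[j]
  list(I = cumI[j] + .seg_I(u0[j], seg$beta[j], k, ds),
       J = cumJ[j] + .seg_J(u0[j], seg$beta[j], k, ds))
}

.check_domain <- function(profile, t) {
  dur <- profile_duration(profile)
  if (!is.numeric(t) || anyNA(t)) stop("times must be numeric", call. = FALSE)
  if (any(t < 0 | t > dur)) {
    bad <- t[t < 0 | t > dur][1]
    stop("time ", bad, " outside profile domain [0, ", dur, "]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Accumulated log-reduction integral
#'
#' Computes `I(t) = integral_0^t 10^((T(tau) - T_ref)/z) dtau`, evaluated
#' exactly on each linear segment of the profile, so that the survivor
#' curve is `logN(t) = logN0 - I(t)/D_ref`. `I` is in minutes: it equals
#' the treatment time at the reference temperature with the same lethal
#' effect.
#'
#' @inheritParams temperature_at
#' @param params A [bigelow_params()].
#' @param t Times (min) within the profile domain; vectorized.
#' @return Numeric vector `I(t)` (dimensionless times minutes).
#' @export
#' @examples
#' log_reduction_integral(built_in_profile("A"), bigelow_params(), 60)
log_reduction_integral <- function(profile, params, t) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(params, "bigelow_params"))
  .check_domain(profile, t)
  .kinetic_integrals(profile, params, t)$I
}

#' Predicted survivor curve under a dynamic profile
#'
#' @inheritParams log_reduction_integral
#' @param times Times (min) within the profile domain.
#' @return Numeric vector of `logN(t)` (log10 CFU/ml).
#' @export
predict_logN <- function(profile, params, times) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(params, "bigelow_params"))
  .check_domain(profile, times)
  params$logN0 - .kinetic_integrals(profile, params, times)$I / params$D_ref
}

#' Local sensitivity functions of the log count
#'
#' Derivatives of the model output `logN(t)` with respect to the two
#' kinetic parameters, along the trajectory:
#' `sens_D = d logN / d D_ref = I(t) / D_ref^2` and
#' `sens_z = d logN / d z =
#'   (ln 10 / (D_ref z^2)) * integral_0^t (T - T_ref) 10^((T - T_ref)/z) dtau`,
#' both evaluated in closed form per linear segment. The finite-difference
#' method (`method = "fd"`) applies central differences to
#' [predict_logN()] and is provided as an independent cross-check.
#'
#' @inheritParams predict_logN
#' @param method `"analytic"` (default, closed form) or `"fd"` (central
#'   finite differences).
#' @param fd_rel_step Relative step for `method = "fd"`.
#' @return A list with numeric vectors `sens_D` (per min) and `sens_z`
#'   (per degC).
#' @export
local_sensitivities <- function(profile, params, times,
                                method = c("analytic", "fd"),
                                fd_rel_step = 1e-6) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(params, "bigelow_params"))
  method <- match.arg(method)
  .check_domain(profile, times)
  if (method == "analytic") {
    ki <- .kinetic_integrals(profile, params, times)
    out <- list(sens_D = ki$I / params$D_ref^2,
                sens_z = log(10) / (params$D_ref * params$z^2) * ki$J)
  } else {
    hD <- fd_rel_step * params$D_ref
    hz <- fd_rel_step * params$z
    pp <- function(D, z) {
      predict_logN(profile,
                   bigelow_params(D, z, params$T_ref, params$logN0), times)
    }
    out <- list(
      sens_D = (pp(params$D_ref + hD, params$z) -
                  pp(params$D_ref - hD, params$z)) / (2 * hD),
      sens_z = (pp(params$D_ref, params$z + hz) -
                  pp(params$D_ref, params$z - hz)) / (2 * hz))
  }
  if (any(!is.finite(out$sens_D)) || any(!is.finite(out$sens_z))) {
    bad <- times[!is.finite(out$sens_D) | !is.finite(out$sens_z)][1]
    stop("non-finite sensitivity at time ", bad, call. = FALSE)
  }
  out
}

#' Parameter-scaled sensitivity functions
#'
#' Each raw sensitivity multiplied by its nominal parameter value
#' (`D_ref * sens_D`, `z * sens_z`), giving dimensionless-parameter
#' scaling for plots and diagnostics. Extrema locations are unchanged.
#'
#' @inheritParams local_sensitivities
#' @return A list with `sens_D` and `sens_z`, scaled.
#' @export
scaled_sensitivities <- function(profile, params, times) {
  s <- local_sensitivities(profile, params, times)
  list(sens_D = params$D_ref * s$sens_D, sens_z = params$z * s$sens_z)
}

#' Survivor-curve prediction table
#'
#' Convenience assembly of the prediction and both sensitivity functions,
#' in the package's export layout (`time_min,logN,sens_D,sens_z`).
#'
#' @inheritParams local_sensitivities
#' @return A `data.frame` with columns `time_min`, `logN`, `sens_D`,
#'   `sens_z`.
#' @export
survival_prediction <- function(profile, params, times) {
  s <- local_sensitivities(profile, params, times)
  data.frame(time_min = times,
             logN = predict_logN(profile, params, times),
             sens_D = s$sens_D, sens_z = s$sens_z)
}
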