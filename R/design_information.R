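#' Sampling design
#'
#' An ordered set of measurement times within a treatment window. Times
#' are sorted on construction.
#'
#' @param times Numeric vector of sampling times (min), each >= 0.
#' @param profile Optional [temperature_profile()]; when given, times are
#'   checked against `[0, profile_duration(profile)]`.
#' @return An object of class `sampling_design` (a sorted numeric vector).
#' @export
sampling_design <- function(times, profile = NULL) {
  if (!is.numeric(times) || length(times) < 1 || anyNA(times) ||
      any(!is.finite(times))) {
    stop("times must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(times < 0)) stop("sampling times must be >= 0", call. = FALSE)
  if (!is.null(profile)) .check_domain(profile, times)
  structure(sort(as.numeric(times)), class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("Sampling design with", length(x), "points (min):\n ",
      paste(signif(unclass(x), 6), collapse = ", "), "\n")
  invisible(x)
}

#' Uniform (equally spaced) sampling design
#'
#' `n` equally spaced times over `[0, duration]` including both endpoints
#' (`n = 1` gives the midpoint).
#'
#' @param n Number of sampling points (>= 1).
#' @param duration Treatment duration (min).
#' @return A [sampling_design()].
#' @export
#' @examples
#' uniform_design(3, 60) # 0, 30, 60
uniform_design <- function(n, duration) {
  stopifnot(n >= 1, duration > 0)
  if (n == 1) return(sampling_design(duration / 2))
  sampling_design(seq(0, duration, length.out = n))
}

.sensitivity_matrix <- function(times, profile, params, scaled = FALSE) {
  s <- if (scaled) scaled_sensitivities(profile, params, times)
       else local_sensitivities(profile, params, times)
  cbind(sens_D = s$sens_D, sens_z = s$sens_z)
}

#' Fisher Information Matrix of a sampling design
#'
#' Sum over sampling points of the outer product of the local sensitivity
#' vector `(sens_D(t_i), sens_z(t_i))`, with identity weighting. Its
#' determinant is the D-criterion; the inverse FIM lower-bounds the
#' parameter covariance (Cramer-Rao), so `1/det` estimates the volume of
#' the confidence ellipsoid.
#'
#' By default the sensitivities are parameter-scaled
#' ([scaled_sensitivities()]), so information is measured on a
#' dimensionless-parameter scale. This keeps the determinant commensurate
#' with the spacing penalty of [penalized_objective()]; set
#' `scaled = FALSE` for raw sensitivities (the determinant then differs
#' by the constant factor `(D_ref * z)^2`, which cancels whenever two
#' designs are compared).
#'
#' @param design A [sampling_design()] (or numeric vector of times).
#' @inheritParams local_sensitivities
#' @param scaled Use parameter-scaled sensitivities (default) or raw ones.
#' @return A symmetric 2x2 matrix (rows/cols `D_ref`, `z`).
#' @export
fim <- function(design, profile, params, scaled = TRUE) {
  times <- as.numeric(design)
  .check_domain(profile, times)
  S <- .sensitivity_matrix(times, profile, params, scaled)
  m <- crossprod(S)
  dimnames(m) <- list(c("D_ref", "z"), c("D_ref", "z"))
  m
}

# Penalty for one vector of gaps (min). Barrier below t_min, decaying
# above, capped at 1e5 per gap so the objective stays finite at g = t_min.
# The exponential tail is defined on the seconds scale (the minimum
# spacing is a seconds-level constraint), so it is negligible once a gap
# clears the threshold by a few seconds.
.gap_penalty <- function(g, t_min) {
  ifelse(g < t_min,
         (2 - g / t_min) * 1e5,
         pmin(exp(1 / (60 * (g - t_min))) - 1, 1e5))
}

#' Minimum-spacing barrier penalty of a design
#'
#' Sum over adjacent gaps `g` of the sorted sampling times of
#' `P(g) = (2 - g/t_min) * 1e5` for `g < t_min` and
#' `min(exp(1/(g - t_min)) - 1, 1e5)` for `g >= t_min`. The cap resolves
#' the divergence at `g = t_min` and keeps the penalized objective
#' bounded. A single-point design has no gaps and zero penalty.
#'
#' @inheritParams fim
#' @param t_min Minimum admissible time between samples (min); the
#'   default 0.05 min is 3 seconds.
#' @return Total penalty (dimensionless).
#' @export
spacing_penalty <- function(design, t_min = 0.05) {
  if (!is.numeric(t_min) || length(t_min) != 1 || !is.finite(t_min) ||
      t_min <= 0) {
    stop("t_min must be a single positive number", call. = FALSE)
  }
  times <- sort(as.numeric(design))
  if (length(times) < 2) return(0)
  sum(.gap_penalty(diff(times), t_min))
}

#' Penalized D-optimality objective of a design
#'
#' Combines the FIM determinant with the minimum-spacing penalty:
#' `objective = det(FIM) - penalty`. This is the quantity the design
#' optimizer maximizes.
#'
#' @inheritParams spacing_penalty
#' @inheritParams fim
#' @return An object of class `fim_summary`: list with `matrix`, `det`,
#'   `inv_det` (`NA` when `det == 0`), `penalty`, `objective`, `n`.
#' @export
penalized_objective <- function(design, profile, params, t_min = 0.05,
                                scaled = TRUE) {
  m <- fim(design, profile, params, scaled = scaled)
  d <- m[1, 1] * m[2, 2] - m[1, 2]^2
  d <- max(d, 0)  # clamp tiny negative round-off; FIM is PSD by construction
  pen <- spacing_penalty(design, t_min)
  structure(
    list(matrix = m, det = d,
         inv_det = if (d > 0) 1 / d else NA_real_,
         penalty = pen, objective = d - pen,
         n = length(as.numeric(design))),
    class = "fim_summary"
  )
}

#' @export
print.fim_summary <- function(x, ...) {
  cat(sprintf(
    "FIM summary (n = %d): det = %.6g, 1/det = %s, penalty = %.6g, objective = %.6g\n",
    x$n, x$det, if (is.na(x$inv_det)) "undefined" else sprintf("%.6g", x$inv_det),
    x$penalty, x$objective))
  invisible(x)
}
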