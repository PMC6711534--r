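#' Information content versus number of sampling points
#'
#' For each `n` in `n_range`, computes the FIM determinant (and its
#' inverse) of the uniform endpoint-inclusive design and of the
#' D-optimal design found by [optimize_design()]. The optimizer seed is
#' derived deterministically from `seed` and `n`.
#'
#' @inheritParams optimize_design
#' @param n_range Integer vector of design sizes (default 3:20).
#' @return A `data.frame` with columns `profile`, `design_type`
#'   (`uniform`/`oed`), `n`, `det`, `inv_det`, `penalty`, `objective`.
#'   Within each `n`, `oed` det is never below `uniform` det.
#' @export
fim_vs_n <- function(profile, params, n_range = 3:20, t_min = 0.05,
                     seed = 1L, budget = 2e4) {
  dur <- profile_duration(profile)
  rows <- lapply(n_range, function(n) {
    u <- uniform_design(n, dur)
    us <- penalized_objective(u, profile, params, t_min)
    o <- optimize_design(profile, params, n, t_min,
                         seed = seed + 1000L * n, budget = budget)
    os <- o$summary
    data.frame(profile = profile$name,
               design_type = c("uniform", "oed"), n = n,
               det = c(us$det, os$det),
               inv_det = c(us$inv_det, os$inv_det),
               penalty = c(us$penalty, os$penalty),
               objective = c(us$objective, os$objective))
  })
  do.call(rbind, rows)
}

#' Uniform-design size matching a small optimal design
#'
#' Finds the smallest number of uniformly spaced sampling points whose
#' raw FIM determinant (penalty excluded) reaches that of a D-optimal
#' design with `oed_n` points on the same profile — i.e. how many uniform
#' samples it takes to buy the information of a small optimized schedule.
#'
#' @inheritParams optimize_design
#' @param oed_n Size of the reference optimal design (default 3).
#' @param max_n Largest uniform size tried before giving up.
#' @param reference_design Optional [sampling_design()] to use as the
#'   reference instead of running the optimizer (e.g. for validation).
#' @return The smallest matching uniform `n` (integer), or `NA` if no
#'   `n <= max_n` suffices.
#' @export
uniform_equivalent_n <- function(profile, params, oed_n = 3, t_min = 0.05,
                                 seed = 1L, budget = 2e4, max_n = 100L,
                                 reference_design = NULL) {
  stopifnot(oed_n >= 1)
  if (is.null(reference_design)) {
    reference_design <- optimize_design(profile, params, oed_n, t_min,
                                        seed = seed, budget = budget)$design
  }
  target <- penalized_objective(reference_design, profile, params, t_min)$det
  dur <- profile_duration(profile)
  for (n in seq_len(max_n)) {
    d <- penalized_objective(uniform_design(n, dur), profile, params,
                             t_min)$det
    if (d >= target) return(n)
  }
  NA_integer_
}

#' Monte Carlo precision versus number of sampling points
#'
#' Runs the full simulate-and-refit precision pipeline
#' ([monte_carlo_precision()]) for uniform and/or optimal designs across
#' a range of design sizes, collecting mean per-fit standard errors and
#' empirical SDs of the estimates for each cell.
#'
#' @inheritParams monte_carlo_precision
#' @inheritParams fim_vs_n
#' @param design_types Subset of `c("uniform", "oed")`.
#' @return A `data.frame` with one row per (design_type, n): `profile`,
#'   `design_type`, `n`, `convergence_rate`, `frac_precise_D`,
#'   `frac_precise_z`, `mean_se_D`, `mean_se_z`, `empirical_sd_D`,
#'   `empirical_sd_z`.
#' @export
precision_vs_n <- function(profile, params, n_range = 3:20,
                           design_types = c("uniform", "oed"),
                           sigma = 0.25, n_reps = 3, n_sims = 100,
                           threshold = 0.1, t_min = 0.05, seed = 1L,
                           budget = 2e4, fit_logN0 = TRUE) {
  design_types <- match.arg(design_types, c("uniform", "oed"),
                            several.ok = TRUE)
  dur <- profile_duration(profile)
  rows <- list()
  for (n in n_range) {
    for (type in design_types) {
      d <- if (type == "uniform") uniform_design(n, dur)
           else optimize_design(profile, params, n, t_min,
                                seed = seed + 1000L * n,
                                budget = budget)$design
      mc <- monte_carlo_precision(d, profile, params, sigma, n_reps,
                                  n_sims, threshold,
                                  seed = seed + 10L * n +
                                    ifelse(type == "oed", 5L, 0L),
                                  fit_logN0 = fit_logN0)
      rows[[length(rows) + 1L]] <- data.frame(
        profile = profile$name, design_type = type, n = n,
        convergence_rate = mc$convergence_rate,
        frac_precise_D = unname(mc$fraction_precise["D_ref"]),
        frac_precise_z = unname(mc$fraction_precise["z"]),
        mean_se_D = unname(mc$mean_se["D_ref"]),
        mean_se_z = unname(mc$mean_se["z"]),
        empirical_sd_D = unname(mc$empirical_sd["D_ref"]),
        empirical_sd_z = unname(mc$empirical_sd["z"]))
    }
  }
  do.call(rbind, rows)
}
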