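# Run expr with its own RNG stream; the caller's .Random.seed is restored.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Batch evaluation of the penalized objective for a matrix of candidate
# designs (one design per row, rows already sorted ascending). Returns
# list(objective, det, min_gap), vectorized across rows.
.objective_batch <- function(times_mat, profile, params, t_min) {
  m <- nrow(times_mat)
  n <- ncol(times_mat)
  s <- scaled_sensitivities(profile, params, as.numeric(times_mat))
  sD <- matrix(s$sens_D, m, n)
  sz <- matrix(s$sens_z, m, n)
  a <- rowSums(sD * sD)
  b <- rowSums(sD * sz)
  cc <- rowSums(sz * sz)
  det <- pmax(a * cc - b * b, 0)
  if (n >= 2) {
    gaps <- times_mat[, -1, drop = FALSE] - times_mat[, -n, drop = FALSE]
    pen <- rowSums(matrix(.gap_penalty(as.numeric(gaps), t_min), m, n - 1L))
    min_gap <- apply(gaps, 1, min)
  } else {
    pen <- rep(0, m)
    min_gap <- rep(Inf, m)
  }
  list(objective = det - pen, det = det, min_gap = min_gap)
}

# Selection with the spacing tie-break: a challenger wins if its objective
# is larger by more than tol, or within tol but with a larger minimum gap.
.beats <- function(obj_new, gap_new, obj_old, gap_old, tol = 1e-9) {
  (obj_new > obj_old + tol) |
    (abs(obj_new - obj_old) <= tol & gap_new > gap_old)
}

#' D-optimal sampling-time design by global search
#'
#' Maximizes the penalized D-criterion ([penalized_objective()]) over `n`
#' sampling times in `[0, duration]` with a differential-evolution-style
#' population search: decision vectors are kept sorted, the uniform design
#' is injected into the initial population (so the result is never worse
#' than uniform), and the whole search is deterministic for a fixed seed.
#'
#' @inheritParams penalized_objective
#' @param n Number of sampling points (>= 1).
#' @param seed Integer seed controlling the stochastic search.
#' @param budget Total objective evaluations (default 2e4).
#' @param pop_size Population size of the search.
#' @return An object of class `oed_result`: list with `design`
#'   ([sampling_design()]), `summary` ([penalized_objective()] recomputed
#'   on the returned design), `profile_name`, `duration`, `n`, `seed`,
#'   `evaluations`, `converged`, and `trace` (best objective per
#'   generation).
#' @export
#' @examples
#' \donttest{
#' res <- optimize_design(built_in_profile("A"), bigelow_params(), n = 5,
#'                        seed = 1, budget = 4000)
#' res$design
#' }
optimize_design <- function(profile, params, n, t_min = 0.05, seed = 1L,
                            budget = 2e4, pop_size = 20L) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(params, "bigelow_params"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  dur <- profile_duration(profile)
  if (n * t_min > dur) {
    stop("infeasible design: ", n, " points with minimum spacing ", t_min,
         " min cannot fit in a ", dur, " min treatment", call. = FALSE)
  }
  if (budget < 2 * pop_size) stop("budget too small", call. = FALSE)

  .with_seed(seed, {
    Fw <- 0.8; CR <- 0.9
    pop <- matrix(stats::runif(pop_size * n, 0, dur), pop_size, n)
    pop[1, ] <- as.numeric(uniform_design(n, dur))
    pop <- t(apply(pop, 1, sort))
    if (n == 1) pop <- matrix(pop, pop_size, 1)
    ev <- .objective_batch(pop, profile, params, t_min)
    fit <- ev$objective; gap <- ev$min_gap
    evals <- pop_size
    gens <- (budget - pop_size) %/% pop_size
    trace <- numeric(gens + 1L)
    trace[1L] <- max(fit)

    for (g in seq_len(gens)) {
      idx <- t(vapply(seq_len(pop_size), function(i)
        sample(seq_len(pop_size)[-i], 3L), integer(3)))
      mut <- pop[idx[, 1], , drop = FALSE] +
        Fw * (pop[idx[, 2], , drop = FALSE] - pop[idx[, 3], , drop = FALSE])
      cross <- matrix(stats::runif(pop_size * n) < CR, pop_size, n)
      # guarantee at least one mutated coordinate per member
      forced <- cbind(seq_len(pop_size),
                      sample.int(n, pop_size, replace = TRUE))
      cross[forced] <- TRUE
      trial <- ifelse(cross, mut, pop)
      trial <- pmin(pmax(trial, 0), dur)
      trial <- t(apply(trial, 1, sort))
      if (n == 1) trial <- matrix(trial, pop_size, 1)
      tev <- .objective_batch(trial, profile, params, t_min)
      evals <- evals + pop_size
      win <- .beats(tev$objective, tev$min_gap, fit, gap)
      pop[win, ] <- trial[win, ]
      fit[win] <- tev$objective[win]
      gap[win] <- tev$min_gap[win]
      trace[g + 1L] <- max(fit)
    }

    best <- which.max(fit)
    # among ties within 1e-9 pick the largest minimum gap
    tied <- which(abs(fit - fit[best]) <= 1e-9)
    best <- tied[which.max(gap[tied])]
    design <- sampling_design(pop[best, ], profile)

    # converged: best objective stabilized over the final 10% of generations
    tail_n <- max(2L, ceiling(length(trace) * 0.1))
    tail_tr <- utils::tail(trace, tail_n)
    converged <- (tail_tr[tail_n] - tail_tr[1]) <=
      1e-9 * max(1, abs(tail_tr[tail_n]))
    if (!converged) {
      warning("design search still improving when the evaluation budget ",
              "was exhausted; returning best design found", call. = FALSE)
    }

    structure(
      list(design = design,
           summary = penalized_objective(design, profile, params, t_min),
           profile_name = profile$name, duration = dur, n = n,
           t_min = t_min, seed = seed, evaluations = evals,
           converged = converged, trace = trace),
      class = "oed_result"
    )
  })
}

#' @export
print.oed_result <- function(x, ...) {
  cat(sprintf(
    "D-optimal design for profile '%s' (n = %d, seed = %d, %d evaluations%s)\n",
    x$profile_name, x$n, x$seed, x$evaluations,
    if (x$converged) "" else ", not converged"))
  print(x$design)
  print(x$summary)
  invisible(x)
}

#' Frequency table of optimized sampling times
#'
#' Bins the sampling times of one or more design-search results into time
#' bins, stratified by the number of points `n` of each design: the data
#' behind a stacked frequency bar plot of where the optimizer places
#' samples.
#'
#' @param results A single `oed_result` or a list of them; all must share
#'   the same profile.
#' @param bin_width Bin width (min). Bins are `[0, w), [w, 2w), ...` with
#'   the last bin closed at the treatment duration.
#' @return A `data.frame` with columns `bin_left`, `bin_right`,
#'   `n_points`, `count`; zero rows for empty input.
#' @export
design_frequency_table <- function(results, bin_width) {
  if (inherits(results, "oed_result")) results <- list(results)
  stopifnot(is.list(results), bin_width > 0)
  empty <- data.frame(bin_left = numeric(0), bin_right = numeric(0),
                      n_points = integer(0), count = integer(0))
  if (length(results) == 0) return(empty)
  if (!all(vapply(results, inherits, logical(1), "oed_result"))) {
    stop("results must be oed_result objects", call. = FALSE)
  }
  profs <- vapply(results, function(r) r$profile_name, character(1))
  durs <- vapply(results, function(r) r$duration, numeric(1))
  if (length(unique(profs)) > 1 || length(unique(durs)) > 1) {
    stop("all results must share the same profile", call. = FALSE)
  }
  dur <- durs[1]
  breaks <- seq(0, dur, by = bin_width)
  if (breaks[length(breaks)] < dur) breaks <- c(breaks, dur)
  nb <- length(breaks) - 1L
  rows <- lapply(results, function(r) {
    tvec <- as.numeric(r$design)
    j <- findInterval(tvec, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    data.frame(bin_left = breaks[-length(breaks)],
               bin_right = breaks[-1],
               n_points = r$n,
               count = tabulate(j, nbins = nb))
  })
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(count ~ bin_left + bin_right + n_points, out, sum)
  agg[order(agg$n_points, agg$bin_left), , drop = FALSE]
}
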