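#' Piecewise-linear temperature profile
#'
#' A dynamic thermal treatment is represented as a piecewise-linear
#' time-temperature function: temperatures at a set of anchor times, with
#' linear interpolation in between. Time is in minutes, temperature in
#' degrees Celsius, everywhere in the package.
#'
#' @param anchor_times Numeric vector of anchor times (min). Must be strictly
#'   increasing, start at 0, and contain at least two values.
#' @param anchor_temps Numeric vector of temperatures (degC) at the anchors;
#'   same length as `anchor_times`, all finite.
#' @param name Free-text profile name.
#'
#' @return An object of class `temperature_profile` with fields
#'   `anchor_times`, `anchor_temps` and `name`.
#' @seealso [built_in_profile()], [temperature_at()], [profile_duration()]
#' @export
#' @examples
#' p <- temperature_profile(c(0, 10, 20), c(40, 60, 40), "spike")
#' temperature_at(p, 5)
temperature_profile <- function(anchor_times, anchor_temps, name = "custom") {
  if (!is.numeric(anchor_times) || !is.numeric(anchor_temps)) {
    stop("anchor_times and anchor_temps must be numeric", call. = FALSE)
  }
  if (length(anchor_times) != length(anchor_temps)) {
    stop("anchor_times and anchor_temps must have the same length",
         call. = FALSE)
  }
  if (length(anchor_times) < 2) {
    stop("a temperature profile needs at least 2 anchors", call. = FALSE)
  }
  if (anyNA(anchor_times) || anyNA(anchor_temps) ||
      any(!is.finite(anchor_times)) || any(!is.finite(anchor_temps))) {
    stop("anchor times and temperatures must be finite", call. = FALSE)
  }
  if (any(diff(anchor_times) <= 0)) {
    stop("anchor_times must be strictly increasing", call. = FALSE)
  }
  if (anchor_times[1] != 0) {
    stop("the first anchor time must be 0", call. = FALSE)
  }
  structure(
    list(anchor_times = as.numeric(anchor_times),
         anchor_temps = as.numeric(anchor_temps),
         name = as.character(name)[1]),
    class = "temperature_profile"
  )
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat("Temperature profile '", x$name, "'\n", sep = "")
  cat("  duration:", profile_duration(x), "min,",
      length(x$anchor_times), "anchors\n")
  cat("  anchors (min -> degC):",
      paste(sprintf("(%g, %g)", x$anchor_times, x$anchor_temps),
            collapse = " "), "\n")
  invisible(x)
}

#' Duration of a temperature profile
#'
#' @param profile A [temperature_profile()].
#' @return The last anchor time (min).
#' @export
profile_duration <- function(profile) {
  stopifnot(inherits(profile, "temperature_profile"))
  profile$anchor_times[length(profile$anchor_times)]
}

#' Built-in case-study temperature profiles
#'
#' Three canonical dynamic treatments used throughout the package:
#' \describe{
#'   \item{A}{slow monotonic heating, 30 to 60 degC at 0.5 degC/min
#'     (60 min).}
#'   \item{B}{biphasic, 30 to 60 degC at 1 degC/min then cooling back to
#'     30 degC at -1 degC/min (60 min total).}
#'   \item{C}{fast monotonic heating, 45 to 65 degC at 10 degC/min (2 min).}
#' }
#'
#' @param name One of `"A"`, `"B"`, `"C"`.
#' @return A [temperature_profile()].
#' @export
#' @examples
#' built_in_profile("A")
built_in_profile <- function(name) {
  switch(as.character(name)[1],
    A = temperature_profile(c(0, 60), c(30, 60), "A"),
    B = temperature_profile(c(0, 30, 60), c(30, 60, 30), "B"),
    C = temperature_profile(c(0, 2), c(45, 65), "C"),
    stop("unknown profile '", name, "'; valid names are A, B, C",
         call. = FALSE)
  )
}

#' Evaluate a temperature profile
#'
#' Linear interpolation between anchors; no extrapolation outside the
#' profile domain.
#'
#' @param profile A [temperature_profile()].
#' @param t Times (min), each in `[0, profile_duration(profile)]`.
#' @return Temperatures (degC) at `t`.
#' @export
temperature_at <- function(profile, t) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (!is.numeric(t) || anyNA(t)) stop("t must be numeric", call. = FALSE)
  dur <- profile_duration(profile)
  if (any(t < 0 | t > dur)) {
    bad <- t[t < 0 | t > dur][1]
    stop("time ", bad, " outside profile domain [0, ", dur, "]",
         call. = FALSE)
  }
  stats::approx(profile$anchor_times, profile$anchor_temps, xout = t,
                method = "linear", ties = "ordered")$y
}

#' Read / write a temperature profile CSV
#'
#' The file format is a two-column CSV with header `time_min,temp_C`
#' (UTF-8, dot decimal separator). Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param name Profile name to attach; defaults to the file name.
#' @return `read_profile_csv()` returns a [temperature_profile()];
#'   `write_profile_csv()` returns `path` invisibly.
#' @export
read_profile_csv <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "character",
                        check.names = FALSE)
  if (!identical(names(df), c("time_min", "temp_C"))) {
    stop("profile CSV must have columns 'time_min,temp_C'; found: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  if (nrow(df) < 2) {
    stop("profile CSV needs at least 2 rows (anchors); found ", nrow(df),
         call. = FALSE)
  }
  tt <- suppressWarnings(as.numeric(df$time_min))
  TT <- suppressWarnings(as.numeric(df$temp_C))
  if (anyNA(tt)) {
    stop("non-numeric time_min at row ", which(is.na(tt))[1], call. = FALSE)
  }
  if (anyNA(TT)) {
    stop("non-numeric temp_C at row ", which(is.na(TT))[1], call. = FALSE)
  }
  if (any(diff(tt) <= 0)) {
    stop("times not strictly increasing at row ", which(diff(tt) <= 0)[1] + 1,
         call. = FALSE)
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  temperature_profile(tt, TT, name)
}

#' @param profile A [temperature_profile()] to write.
#' @rdname read_profile_csv
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "temperature_profile"))
  utils::write.csv(
    data.frame(time_min = profile$anchor_times,
               temp_C = profile$anchor_temps),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
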