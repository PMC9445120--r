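#' Sampling schedule for sparse Patlak imaging
#'
#' A schedule couples the plasma sampling times with the imaging time
#' points. Plasma is always sampled at t = 0 in addition to every imaging
#' time (so three imaging points give four plasma samples for the
#' trapezoidal AUC); the imaging times themselves are the Patlak regression
#' points.
#'
#' @param imaging_times Imaging time points in hours post-injection,
#'   strictly positive and distinct; sorted internally. At least 2 are
#'   required for a Patlak fit; the canonical design uses 3 drawn from
#'   24, 48, 96, 144, 192 h.
#' @return An object of class `"sampling_schedule"` with elements
#'   `plasma_times` (leading 0 followed by the imaging times) and
#'   `imaging_times`.
#' @examples
#' sampling_schedule(c(24, 48, 96))
#' @export
sampling_schedule <- function(imaging_times) {
  if (!is.numeric(imaging_times) || length(imaging_times) < 2L ||
      anyNA(imaging_times)) {
    stop("imaging_times must be >= 2 numeric time points", call. = FALSE)
  }
  if (any(imaging_times <= 0)) {
    stop("imaging times must be strictly positive (t = 0 is plasma-only)",
         call. = FALSE)
  }
  imaging_times <- sort(imaging_times)
  if (anyDuplicated(imaging_times)) {
    stop("imaging times must be distinct", call. = FALSE)
  }
  structure(list(plasma_times = c(0, imaging_times),
                 imaging_times = imaging_times),
            class = "sampling_schedule")
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat("Sampling schedule: plasma at {",
      paste(x$plasma_times, collapse = ", "), "} h; imaging at {",
      paste(x$imaging_times, collapse = ", "), "} h p.i.\n")
  invisible(x)
}

#' @export
format.sampling_schedule <- function(x, ...) {
  paste(x$imaging_times, collapse = "-")
}

#' Enumerate candidate imaging schedules
#'
#' All size-`k` subsets of the candidate imaging times, in ascending order,
#' optionally restricted to subsets containing a required time point. With
#' the canonical candidates 24, 48, 96, 144, 192 h and `k = 3` this yields
#' the 10 possible three-scan designs (6 of which include 24 h).
#'
#' @param candidates Candidate imaging times (h).
#' @param k Number of imaging time points per schedule.
#' @param require_time Optional time point every schedule must contain.
#' @return A list of [sampling_schedule()] objects (possibly empty when
#'   `require_time` is not among `candidates`).
#' @examples
#' length(enumerate_schedules(c(24, 48, 96, 144, 192), 3))            # 10
#' length(enumerate_schedules(c(24, 48, 96, 144, 192), 3, 24))        # 6
#' @export
enumerate_schedules <- function(candidates = c(24, 48, 96, 144, 192), k = 3,
                                require_time = NULL) {
  candidates <- sort(unique(candidates))
  if (k > length(candidates)) {
    stop("k may not exceed the number of candidate times", call. = FALSE)
  }
  sets <- utils::combn(candidates, k, simplify = FALSE)
  if (!is.null(require_time)) {
    sets <- Filter(function(s) require_time %in% s, sets)
  }
  lapply(sets, sampling_schedule)
}
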