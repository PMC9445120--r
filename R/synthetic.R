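#' Generator specification for random antibody-like input functions
#'
#' Ranges from which [random_input_function()] draws: fast- and slow-phase
#' half-lives, the concentration at t = 0 and the fraction of that
#' concentration carried by the fast phase. The defaults bracket the
#' clearances of the bundled fixtures, from fast huJ591-like to slow
#' pertuzumab-like profiles.
#'
#' @param fast_half_life Range (h) of the fast-phase half-life.
#' @param slow_half_life Range (h) of the slow-phase half-life; must lie
#'   entirely above `fast_half_life`.
#' @param conc0 Range of the t = 0 concentration (%IA/L).
#' @param fast_fraction Range in (0, 1) of the fast-phase amplitude
#'   fraction.
#' @return A list of class `"if_generator_spec"`.
#' @examples
#' if_generator_spec()
#' @export
if_generator_spec <- function(fast_half_life = c(4, 12),
                              slow_half_life = c(40, 170),
                              conc0 = c(25, 40),
                              fast_fraction = c(0.3, 0.6)) {
  rng <- function(x, nm, lo = 0, hi = Inf) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
        x[1] > x[2] || x[1] <= lo || x[2] >= hi) {
      stop("invalid range for ", nm, call. = FALSE)
    }
    x
  }
  rng(fast_half_life, "fast_half_life")
  rng(slow_half_life, "slow_half_life")
  rng(conc0, "conc0")
  rng(fast_fraction, "fast_fraction", hi = 1)
  if (slow_half_life[1] <= fast_half_life[2]) {
    stop("slow half-life range must lie above the fast half-life range",
         call. = FALSE)
  }
  structure(list(fast_half_life = fast_half_life,
                 slow_half_life = slow_half_life,
                 conc0 = conc0, fast_fraction = fast_fraction),
            class = "if_generator_spec")
}

#' Draw a random antibody-like input function
#'
#' Samples half-lives, t = 0 concentration and fast fraction uniformly
#' within the spec's ranges and converts them to bi-exponential
#' coefficients (`rate = -log(2)/half_life`, `amp = conc0 * fraction`).
#' Every draw satisfies the [biexp()] invariants. Uses the current RNG
#' stream unless `seed` is given.
#'
#' @param spec An [if_generator_spec()].
#' @param seed Optional seed for a reproducible draw.
#' @param label Label for the drawn input function.
#' @return A [biexp()] object.
#' @examples
#' random_input_function(seed = 1)
#' @export
random_input_function <- function(spec = if_generator_spec(), seed = NULL,
                                  label = "random IF") {
  stopifnot(inherits(spec, "if_generator_spec"))
  draw <- function() {
    u <- function(r) stats::runif(1, r[1], r[2])
    hl_fast <- u(spec$fast_half_life)
    hl_slow <- u(spec$slow_half_life)
    c0 <- u(spec$conc0)
    fr <- u(spec$fast_fraction)
    biexp(amp_fast = c0 * fr, rate_fast = -log(2) / hl_fast,
          amp_slow = c0 * (1 - fr), rate_slow = -log(2) / hl_slow,
          label = label)
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw)
}

#' Build an end-to-end simulation scenario
#'
#' Produces the exact tabular inputs the Patlak fitting front end and the
#' Monte-Carlo engine consume: noise-free plasma samples at the schedule's
#' plasma times and both noise-free and noisy tissue samples at the imaging
#' times. With `noise0 = 0` the noisy curve equals the noise-free one.
#'
#' @param ifn A [biexp()] input function.
#' @param ki,vt Reference kinetic parameters (`vt > 0`).
#' @param schedule A [sampling_schedule()].
#' @param noise0 Fractional SD of the TAC at t = 0.
#' @param seed Optional seed for the noise deviates.
#' @param half_life Isotope half-life (h).
#' @return A list with `plasma` (data frame `time_h`,
#'   `conc_pia_per_l`), `tissue` (data frame `time_h`, `conc_pia_per_l`,
#'   `noisy_conc_pia_per_l`), the generating `condition` and the deviates
#'   `z`.
#' @examples
#' sc <- make_scenario(input_function_library("pertuzumab-like"),
#'                     ki = 1e-3, vt = 0.2,
#'                     schedule = sampling_schedule(c(24, 48, 96)),
#'                     noise0 = 0.05, seed = 11)
#' sc$tissue
#' @export
make_scenario <- function(ifn, ki, vt, schedule, noise0 = 0.05, seed = NULL,
                          half_life = 78.41) {
  cond <- condition(ifn, schedule, ki, vt, noise0, n_reps = 1,
                    seed = seed, half_life = half_life)
  ing <- condition_ingredients(cond)
  k <- length(schedule$imaging_times)
  z <- if (is.null(seed)) stats::rnorm(k) else withr_seed(seed, function()
    stats::rnorm(k))
  noisy <- add_noise(ing$tac, ing$frac_sd, z)
  list(
    plasma = data.frame(time_h = schedule$plasma_times,
                        conc_pia_per_l = ing$plasma),
    tissue = data.frame(time_h = schedule$imaging_times,
                        conc_pia_per_l = ing$tac,
                        noisy_conc_pia_per_l = noisy),
    condition = cond, z = z)
}

#' Write a scenario in the CSV dialect of the fitting front end
#'
#' One row per plasma sample with columns `time_h`, `plasma_pia_per_l`,
#' `tissue_pia_per_l`; the tissue column is empty at t = 0 (plasma-only
#' sample). The noisy tissue values are written.
#'
#' @param scenario A [make_scenario()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_csv <- function(scenario, path) {
  tt <- scenario$plasma$time_h
  tissue <- rep(NA_real_, length(tt))
  m <- match(scenario$tissue$time_h, tt)
  tissue[m] <- scenario$tissue$noisy_conc_pia_per_l
  utils::write.csv(
    data.frame(time_h = tt,
               plasma_pia_per_l = scenario$plasma$conc_pia_per_l,
               tissue_pia_per_l = tissue),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a plasma/tissue sample table and fit Patlak
#'
#' Reads the CSV dialect of [write_scenario_csv()] (columns `time_h`,
#' `plasma_pia_per_l`, `tissue_pia_per_l`, tissue blank where only plasma
#' was sampled), forms the sparse-sampling Patlak coordinates and fits the
#' Patlak line.
#'
#' @param path CSV path.
#' @return A [patlak()] fit.
#' @export
patlak_from_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_h", "plasma_pia_per_l", "tissue_pia_per_l")
  if (!all(need %in% names(d))) {
    stop("CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- d[order(d$time_h), ]
  img <- !is.na(d$tissue_pia_per_l)
  coords <- patlak_coordinates(d$time_h, d$plasma_pia_per_l,
                               d$time_h[img], d$tissue_pia_per_l[img])
  patlak(coords)
}
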