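#' Counting-statistics noise model for tissue activity curves
#'
#' Noise on the tissue activity curve (TAC) is derived from counting
#' statistics: counts are Poisson, so the fractional standard deviation
#' scales as the inverse square root of the number of counts, which (for
#' equal scan durations) is proportional to the non-decay-corrected activity
#' concentration. The model is anchored by a fractional SD at time zero and
#' the physical half-life of the isotope.
#'
#' @param noise0 Fractional SD of the tissue concentration at t = 0
#'   (e.g. 0.05 for 5% noise); must satisfy `0 <= noise0 < 1`.
#' @param half_life Isotope physical half-life in hours; default 78.41 h
#'   (zirconium-89).
#' @return An object of class `"noise_model"`.
#' @examples
#' noise_model(0.05)
#' @export
noise_model <- function(noise0 = 0.05, half_life = 78.41) {
  if (!is.numeric(noise0) || length(noise0) != 1L ||
      noise0 < 0 || noise0 >= 1) {
    stop("noise0 must be a fraction in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(half_life) || length(half_life) != 1L || half_life <= 0) {
    stop("half_life must be a positive number of hours", call. = FALSE)
  }
  structure(list(noise0 = noise0, half_life = half_life),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "Counting-statistics noise model: %.1f%% SD at t = 0, half-life %.2f h\n",
    100 * x$noise0, x$half_life))
  invisible(x)
}

#' Simulate a noise-free tissue activity curve
#'
#' Forward model for the tissue activity concentration of an irreversibly
#' trapped tracer under the Patlak model:
#' \deqn{AC_t(t) = K_i \cdot AUC_p(t) + V_T \cdot AC_p(t),}
#' i.e. the tissue is in equilibrium with plasma from t = 0 onwards. At
#' t = 0 this equals \eqn{V_T (A + B)}.
#'
#' @param ifn A [biexp()] input function.
#' @param ki Net irreversible uptake rate (1/h), >= 0.
#' @param vt Reversible distribution volume (unitless), >= 0.
#' @param times Hours post-injection, all >= 0.
#' @return Tissue activity concentration (%IA/L) at `times`.
#' @examples
#' ifn <- input_function_library("pertuzumab-like")
#' simulate_tac(ifn, ki = 1e-3, vt = 0.2, times = c(24, 48, 96))
#' @export
simulate_tac <- function(ifn, ki, vt, times) {
  stopifnot(inherits(ifn, "biexp"))
  if (!is.numeric(ki) || length(ki) != 1L || ki < 0) {
    stop("ki must be a non-negative scalar (1/h)", call. = FALSE)
  }
  if (!is.numeric(vt) || length(vt) != 1L || vt < 0) {
    stop("vt must be a non-negative scalar", call. = FALSE)
  }
  check_times(times)
  ki * auc(ifn, times) + vt * predict(ifn, times)
}

#' Remove decay correction from an activity concentration
#'
#' PET concentrations are conventionally decay-corrected to injection time;
#' counting statistics, however, are governed by the activity actually
#' present in the scanner. This multiplies by the physical decay factor
#' \eqn{2^{-t/T_{1/2}}}.
#'
#' @param conc Decay-corrected concentration(s).
#' @param times Hours post-injection, >= 0 (recycled against `conc`).
#' @param noise A [noise_model()] carrying the half-life, or a numeric
#'   half-life in hours.
#' @return Non-decay-corrected concentration(s).
#' @examples
#' non_decay_corrected(100, 78.41)  # half of 100
#' @export
non_decay_corrected <- function(conc, times, noise = noise_model()) {
  check_times(times)
  hl <- if (inherits(noise, "noise_model")) noise$half_life else noise
  if (!is.numeric(hl) || length(hl) != 1L || hl <= 0) {
    stop("half-life must be a positive scalar", call. = FALSE)
  }
  conc * 2^(-times / hl)
}

#' Time-dependent fractional SD of the tissue activity curve
#'
#' The fractional SD at time t follows from Poisson counting statistics as
#' \deqn{\%SD(t) = \%SD(0) \sqrt{ncAC_t(0) / ncAC_t(t)},}
#' where \eqn{ncAC_t} is the non-decay-corrected tissue concentration. It
#' equals `noise0` at t = 0 and grows as the non-decay-corrected signal
#' decays, so late frames are noisier.
#'
#' @param tac0 Noise-free tissue concentration at t = 0 (> 0); for the
#'   Patlak forward model this is `vt * (A + B)`.
#' @param tac_t Noise-free tissue concentration(s) at `times` (> 0).
#' @param times Hours post-injection, >= 0.
#' @param noise A [noise_model()].
#' @return Fractional SD at each of `times`.
#' @examples
#' ifn <- input_function_library("pertuzumab-like")
#' tac0 <- simulate_tac(ifn, 1e-3, 0.2, 0)
#' tac <- simulate_tac(ifn, 1e-3, 0.2, c(24, 48, 96))
#' percent_sd(tac0, tac, c(24, 48, 96), noise_model(0.05))
#' @export
percent_sd <- function(tac0, tac_t, times, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.numeric(tac0) || length(tac0) != 1L || tac0 <= 0) {
    stop("tac0 must be a positive scalar concentration", call. = FALSE)
  }
  if (any(tac_t <= 0)) {
    stop("tissue concentrations must be positive for the SD model",
         call. = FALSE)
  }
  check_times(times)
  nc_t <- non_decay_corrected(tac_t, times, noise)
  noise$noise0 * sqrt(tac0 / nc_t) # ncAC_t(0) = tac0: decay factor is 1
}

#' Add multiplicative Gaussian noise to a concentration
#'
#' Applies `conc + conc * frac_sd * z` with `z` a standard-normal deviate,
#' so the expectation over `z` is `conc` and the SD is `conc * frac_sd`.
#' Negative outputs are possible and deliberately retained: truncation
#' would bias the downstream estimator.
#'
#' @param conc Noise-free concentration(s), >= 0.
#' @param frac_sd Fractional SD(s), >= 0.
#' @param z Standard-normal deviate(s); defaults to fresh draws from the
#'   current RNG stream.
#' @return Noisy concentration(s).
#' @examples
#' add_noise(10, 0.1, z = 0)      # exactly 10
#' set.seed(1); add_noise(10, 0.1)
#' @export
add_noise <- function(conc, frac_sd, z = stats::rnorm(length(conc))) {
  if (any(conc < 0)) stop("conc must be non-negative", call. = FALSE)
  if (any(frac_sd < 0)) stop("frac_sd must be non-negative", call. = FALSE)
  conc + conc * frac_sd * z
}
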