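#' Sparse-sampling trapezoidal plasma AUC
#'
#' Composite trapezoidal rule over the sampled plasma points from 0 up to
#' `upto`, which must itself be one of the sample times (no interpolation is
#' performed). For a convex, decreasing input function the trapezoid
#' overestimates the true integral; this overestimation is the mechanism
#' behind the systematic negative bias of sparse-sampling Patlak Ki.
#'
#' @param times Plasma sample times (h), strictly increasing, first element 0.
#' @param values Plasma concentrations (%IA/L) at `times`.
#' @param upto Upper integration limit; must be one of `times`.
#' @return Cumulated concentration (%IA.h/L) from 0 to `upto`.
#' @examples
#' trapezoid_auc(c(0, 24), c(3, 3), 24)  # 72: exact for a constant
#' @export
trapezoid_auc <- function(times, values, upto) {
  if (length(times) != length(values) || length(times) < 2L) {
    stop("times and values must have equal length >= 2", call. = FALSE)
  }
  if (times[1] != 0) stop("plasma sampling must start at t = 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  k <- which(times == upto)
  if (length(k) != 1L) {
    stop("upto must be one of the plasma sample times (no interpolation)",
         call. = FALSE)
  }
  if (k == 1L) return(0)
  tt <- times[seq_len(k)]
  vv <- values[seq_len(k)]
  sum(diff(tt) * (vv[-k] + vv[-1]) / 2)
}

#' Patlak plot coordinates from sampled curves
#'
#' For each imaging time t the Patlak coordinates are
#' \deqn{x = AUC_p(t) / AC_p(t), \qquad y = AC_t(t) / AC_p(t),}
#' with the plasma AUC computed by the sparse trapezoidal rule over the
#' plasma samples. The t = 0 plasma sample contributes only to the AUC; it
#' is never a regression point.
#'
#' @param plasma_times Plasma sample times (h), strictly increasing,
#'   starting at 0, covering all `imaging_times`.
#' @param plasma_conc Plasma concentrations at `plasma_times` (%IA/L).
#' @param imaging_times Imaging time points (h), a subset of
#'   `plasma_times[-1]`.
#' @param tissue_conc Tissue concentrations at `imaging_times` (%IA/L).
#' @return A data frame with columns `time_h`, `x` (normalised time, h) and
#'   `y` (tissue-to-plasma ratio, unitless).
#' @examples
#' ifn <- input_function_library("pertuzumab-like")
#' tt <- c(0, 24, 48, 96)
#' cp <- predict(ifn, tt)
#' ct <- simulate_tac(ifn, 1e-3, 0.2, tt[-1])
#' patlak_coordinates(tt, cp, tt[-1], ct)
#' @export
patlak_coordinates <- function(plasma_times, plasma_conc, imaging_times,
                               tissue_conc) {
  if (length(imaging_times) != length(tissue_conc)) {
    stop("imaging_times and tissue_conc must have equal length", call. = FALSE)
  }
  if (!all(imaging_times %in% plasma_times)) {
    stop("every imaging time must have a plasma sample", call. = FALSE)
  }
  idx <- match(imaging_times, plasma_times)
  cp <- plasma_conc[idx]
  if (any(cp == 0)) {
    stop("zero plasma concentration at an imaging time", call. = FALSE)
  }
  x <- vapply(imaging_times, function(t)
    trapezoid_auc(plasma_times, plasma_conc, t), numeric(1)) / cp
  data.frame(time_h = imaging_times, x = x, y = tissue_conc / cp)
}

# closed-form OLS line; shared by patlak() and the vectorised Monte-Carlo
# path so that both produce numerically identical estimates
ols_line <- function(x, y) {
  xb <- mean(x)
  w <- x - xb
  sxx <- sum(w * w)
  slope <- sum(w * y) / sxx
  c(slope = slope, intercept = mean(y) - slope * xb)
}

#' Patlak graphical analysis
#'
#' Fits the Patlak equation
#' \deqn{AC_t/AC_p = K_i \cdot (AUC_p/AC_p) + V_T}
#' by unweighted ordinary least squares: the slope estimates the net
#' irreversible uptake rate \eqn{K_i} (1/h) and the intercept the
#' reversible distribution volume \eqn{V_T} (unitless). No non-negativity
#' constraint is applied to either estimate, so negative estimates are
#' possible under noise and are reported as such.
#'
#' @param x Patlak x-coordinates (normalised time, h), or a data frame with
#'   columns `x` and `y` as returned by [patlak_coordinates()].
#' @param y Patlak y-coordinates (tissue-to-plasma ratios); ignored when
#'   `x` is a data frame.
#' @return An object of class `"patlak"` with components `coefficients`
#'   (named `Ki`, `VT`), `x`, `y`, `fitted.values`, `residuals` and `call`.
#' @examples
#' f <- patlak(c(30, 60, 90), 0.005 * c(30, 60, 90) + 0.2)
#' coef(f)  # Ki = 0.005, VT = 0.2, exactly
#' @seealso [patlak_coordinates()], [run_condition()]
#' @export
patlak <- function(x, y = NULL) {
  cl <- match.call()
  if (is.data.frame(x)) {
    if (!all(c("x", "y") %in% names(x))) {
      stop("data frame input must have columns 'x' and 'y'", call. = FALSE)
    }
    y <- x$y
    x <- x$x
  }
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L || length(unique(x[ok])) < 2L) {
    stop("Patlak fit requires at least 2 points with distinct x", call. = FALSE)
  }
  b <- ols_line(x[ok], y[ok])
  fit <- structure(
    list(coefficients = c(Ki = unname(b["slope"]), VT = unname(b["intercept"])),
         x = x[ok], y = y[ok], call = cl),
    class = "patlak")
  fit$fitted.values <- b["slope"] * fit$x + b["intercept"]
  fit$residuals <- fit$y - fit$fitted.values
  fit
}

#' @export
coef.patlak <- function(object, ...) object$coefficients

#' @export
print.patlak <- function(x, digits = 6, ...) {
  cat("Patlak graphical analysis (", length(x$x), " points)\n", sep = "")
  cat(sprintf("  Ki = %s 1/h   VT = %s\n",
              format(x$coefficients[["Ki"]], digits = digits),
              format(x$coefficients[["VT"]], digits = digits)))
  invisible(x)
}

#' @export
summary.patlak <- function(object, ...) {
  n <- length(object$x)
  rss <- sum(object$residuals^2)
  sxx <- sum((object$x - mean(object$x))^2)
  sigma2 <- if (n > 2) rss / (n - 2) else NA_real_
  tss <- sum((object$y - mean(object$y))^2)
  out <- list(
    coefficients = cbind(
      Estimate = object$coefficients,
      `Std. Error` = c(sqrt(sigma2 / sxx),
                       sqrt(sigma2 * (1 / n + mean(object$x)^2 / sxx)))),
    sigma = sqrt(sigma2),
    r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n = n, call = object$call)
  class(out) <- "summary.patlak"
  out
}

#' @export
print.summary.patlak <- function(x, digits = 6, ...) {
  cat("Patlak graphical analysis\n\nCoefficients:\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("\nResidual SD: %s on %d points; R-squared: %s\n",
              format(x$sigma, digits = digits), x$n,
              format(x$r.squared, digits = digits)))
  invisible(x)
}

#' @export
predict.patlak <- function(object, x = NULL, ...) {
  if (is.null(x)) return(object$fitted.values)
  object$coefficients[["Ki"]] * x + object$coefficients[["VT"]]
}

#' @export
residuals.patlak <- function(object, ...) object$residuals

#' @export
fitted.patlak <- function(object, ...) object$fitted.values

#' Patlak plot
#'
#' Plots the Patlak coordinates with the fitted regression line.
#'
#' @param x A [patlak()] fit.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.patlak <- function(x, xlab = "AUC_p / AC_p (h)",
                        ylab = "AC_t / AC_p", ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab,
                 main = "Patlak plot", ...)
  graphics::abline(x$coefficients[["VT"]], x$coefficients[["Ki"]],
                   col = "red3")
  invisible(x)
}
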