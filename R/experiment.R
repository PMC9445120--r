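#' Monte-Carlo simulation condition
#'
#' Bundles everything one simulated study needs: an input function, a
#' sampling schedule, reference kinetic parameters, a noise level and the
#' number of repetitions. The reference `vt` must be strictly positive
#' because the counting-statistics noise model anchors its SD ratio at the
#' t = 0 tissue concentration `vt * AC_p(0)`.
#'
#' @param ifn A [biexp()] input function.
#' @param schedule A [sampling_schedule()].
#' @param ki Reference net irreversible uptake rate (1/h), >= 0.
#' @param vt Reference distribution volume (unitless), > 0.
#' @param noise0 Fractional SD of the TAC at t = 0 (e.g. 0.05).
#' @param n_reps Number of Monte-Carlo repetitions (default 1000).
#' @param seed RNG seed for this condition, or `NULL` to draw deviates from
#'   the current RNG stream.
#' @param half_life Isotope half-life in hours (default 78.41, zirconium-89).
#' @return An object of class `"patlak_condition"`.
#' @examples
#' cond <- condition(input_function_library("pertuzumab-like"),
#'                   sampling_schedule(c(24, 48, 96)),
#'                   ki = 1e-3, vt = 0.2, noise0 = 0.05,
#'                   n_reps = 100, seed = 42)
#' run_condition(cond)
#' @export
condition <- function(ifn, schedule, ki, vt, noise0, n_reps = 1000,
                      seed = NULL, half_life = 78.41) {
  stopifnot(inherits(ifn, "biexp"), inherits(schedule, "sampling_schedule"))
  if (!is.numeric(vt) || length(vt) != 1L || vt <= 0) {
    stop("reference vt must be strictly positive (noise model anchor)",
         call. = FALSE)
  }
  if (!is.numeric(ki) || length(ki) != 1L || ki < 0) {
    stop("reference ki must be non-negative", call. = FALSE)
  }
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1) {
    stop("n_reps must be >= 1", call. = FALSE)
  }
  noise <- noise_model(noise0, half_life) # validates noise0 and half_life
  structure(list(ifn = ifn, schedule = schedule, ki = ki, vt = vt,
                 noise = noise, n_reps = as.integer(n_reps), seed = seed),
            class = "patlak_condition")
}

#' @export
print.patlak_condition <- function(x, ...) {
  cat(sprintf(
    "Simulation condition: %s, imaging {%s} h, rKi = %g 1/h, rVT = %g, %g%% noise, %d reps\n",
    if (!is.na(x$ifn$label)) x$ifn$label else "unlabelled IF",
    paste(x$schedule$imaging_times, collapse = ", "),
    x$ki, x$vt, 100 * x$noise$noise0, x$n_reps))
  invisible(x)
}

# noise-free ingredients of a condition: plasma samples, Patlak
# x-coordinates (sparse trapezoidal AUC), noise-free tissue values and
# their per-time fractional SDs
condition_ingredients <- function(cond) {
  sch <- cond$schedule
  plasma <- predict(cond$ifn, sch$plasma_times)
  tac <- simulate_tac(cond$ifn, cond$ki, cond$vt, sch$imaging_times)
  tac0 <- cond$vt * predict(cond$ifn, 0)
  frac_sd <- percent_sd(tac0, tac, sch$imaging_times, cond$noise)
  coords <- patlak_coordinates(sch$plasma_times, plasma,
                               sch$imaging_times, tac)
  list(plasma = plasma, tac = tac, frac_sd = frac_sd,
       x = coords$x, cp = plasma[match(sch$imaging_times, sch$plasma_times)])
}

#' Run a single Monte-Carlo repetition
#'
#' Composes the full pipeline for one simulated study: noise-free TAC at
#' the imaging times, multiplicative counting-statistics noise with the
#' supplied standard-normal deviates, Patlak coordinates with the sparse
#' trapezoidal plasma AUC, and the OLS Patlak fit. Plasma samples carry no
#' noise.
#'
#' @param cond A [condition()].
#' @param z Standard-normal deviates, one per imaging time point; `z = 0`
#'   (recycled) gives the deterministic noise-free estimate, whose only
#'   error is the trapezoidal-AUC bias.
#' @return Named numeric vector `c(ki_hat, vt_hat)`; `NA`s if the
#'   regression is degenerate.
#' @examples
#' cond <- condition(input_function_library("pertuzumab-like"),
#'                   sampling_schedule(c(24, 48, 96)), 1e-3, 0.2, 0.05)
#' run_repetition(cond, z = c(0, 0, 0))
#' @export
run_repetition <- function(cond, z) {
  stopifnot(inherits(cond, "patlak_condition"))
  ing <- condition_ingredients(cond)
  noisy <- add_noise(ing$tac, ing$frac_sd, rep_len(z, length(ing$tac)))
  est <- tryCatch({
    b <- ols_line(ing$x, noisy / ing$cp)
    c(ki_hat = unname(b["slope"]), vt_hat = unname(b["intercept"]))
  }, error = function(e) c(ki_hat = NA_real_, vt_hat = NA_real_))
  if (any(!is.finite(est))) est[] <- NA_real_
  est
}

#' Run a full Monte-Carlo condition
#'
#' Executes `n_reps` repetitions with independent standard-normal deviates
#' (one per imaging time point per repetition) drawn from the condition's
#' seeded stream, and summarises accuracy and precision of the Ki and VT
#' estimates. Because the OLS estimator is linear in the tissue values, the
#' repetitions are evaluated in one vectorised sweep that is numerically
#' identical to repeated [run_repetition()] calls.
#'
#' Percent bias is `100 * (mean(est) - ref) / ref`; percent variability is
#' `100 * sd(est) / ref`, i.e. the spread of a single simulated study
#' relative to the reference value. Degenerate repetitions (non-finite
#' estimates) are excluded from the moments and counted in `n_failed`.
#'
#' @param cond A [condition()]. If `cond$seed` is non-`NULL` the RNG is
#'   seeded locally (the caller's RNG state is preserved).
#' @return A one-row data frame: `if_label`, `t1_h`, `t2_h`, `t3_h`,
#'   `rki_per_h`, `rvt`, `noise_pct`, `n_reps`, `n_failed`,
#'   `ki_noise_free`, `vt_noise_free`, `mean_ki`, `sd_ki`, `bias_ki_pct`,
#'   `variability_ki_pct`, `mean_vt`, `sd_vt`, `bias_vt_pct`,
#'   `variability_vt_pct`.
#' @examples
#' cond <- condition(input_function_library("trastuzumab-like"),
#'                   sampling_schedule(c(24, 48, 96)), 5e-3, 0.2, 0.05,
#'                   n_reps = 200, seed = 7)
#' run_condition(cond)
#' @export
run_condition <- function(cond) {
  stopifnot(inherits(cond, "patlak_condition"))
  ing <- condition_ingredients(cond)
  k <- length(cond$schedule$imaging_times)
  n <- cond$n_reps

  draw <- function() matrix(stats::rnorm(n * k), nrow = n, ncol = k,
                            byrow = TRUE)
  Z <- if (!is.null(cond$seed)) {
    withr_seed(cond$seed, draw)
  } else {
    draw()
  }

  # vectorised OLS: identical arithmetic to ols_line() row by row
  xb <- mean(ing$x)
  w <- ing$x - xb
  sxx <- sum(w * w)
  Y <- sweep(1 + sweep(Z, 2, ing$frac_sd, `*`), 2, ing$tac / ing$cp, `*`)
  ki_hat <- as.vector(Y %*% w) / sxx
  vt_hat <- rowMeans(Y) - ki_hat * xb

  ok <- is.finite(ki_hat) & is.finite(vt_hat)
  nf <- run_repetition(cond, z = rep(0, k))
  summarise_condition(cond, ki_hat[ok], vt_hat[ok], sum(!ok), nf)
}

# seed locally without disturbing the caller's RNG stream
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

summarise_condition <- function(cond, ki_hat, vt_hat, n_failed, noise_free) {
  empty <- length(ki_hat) == 0L
  mean_ki <- if (empty) NA_real_ else mean(ki_hat)
  mean_vt <- if (empty) NA_real_ else mean(vt_hat)
  sd_ki <- if (length(ki_hat) > 1L) stats::sd(ki_hat) else
    if (empty) NA_real_ else 0
  sd_vt <- if (length(vt_hat) > 1L) stats::sd(vt_hat) else
    if (empty) NA_real_ else 0
  it <- cond$schedule$imaging_times
  data.frame(
    if_label = if (!is.na(cond$ifn$label)) cond$ifn$label else "custom",
    t1_h = it[1], t2_h = it[2], t3_h = if (length(it) >= 3) it[3] else NA_real_,
    rki_per_h = cond$ki, rvt = cond$vt, noise_pct = 100 * cond$noise$noise0,
    n_reps = cond$n_reps, n_failed = n_failed,
    ki_noise_free = noise_free[["ki_hat"]],
    vt_noise_free = noise_free[["vt_hat"]],
    mean_ki = mean_ki, sd_ki = sd_ki,
    bias_ki_pct = 100 * (mean_ki - cond$ki) / cond$ki,
    variability_ki_pct = 100 * sd_ki / cond$ki,
    mean_vt = mean_vt, sd_vt = sd_vt,
    bias_vt_pct = 100 * (mean_vt - cond$vt) / cond$vt,
    variability_vt_pct = 100 * sd_vt / cond$vt,
    stringsAsFactors = FALSE)
}

#' Deterministic per-condition sub-seed
#'
#' Derives a reproducible seed for one grid cell from the master seed and a
#' textual condition descriptor via a small multiplicative string hash
#' (computed in doubles, exact below 2^53, reduced mod 2^31 - 1). Adding
#' cells to a grid never perturbs the seeds of existing cells.
#'
#' @param master_seed Integer master seed.
#' @param descriptor Character descriptor of the condition.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' condition_seed(1, "pertuzumab-like|24-48-96|0.001|0.2|0.05")
#' @export
condition_seed <- function(master_seed, descriptor) {
  m <- 2^31 - 1
  h <- 5381
  for (b in utf8ToInt(descriptor)) {
    h <- (h * 131 + b) %% m
  }
  as.integer((h + (master_seed %% m) * 10007) %% (m - 1) + 1)
}

condition_descriptor <- function(if_label, imaging_times, ki, vt, noise0) {
  paste(if_label, paste(imaging_times, collapse = "-"),
        signif(ki, 12), signif(vt, 12), signif(noise0, 12), sep = "|")
}

#' Run a Monte-Carlo grid of simulation conditions
#'
#' Crosses input functions, imaging schedules, reference kinetic parameters
#' and noise levels, runs [run_condition()] for every cell with a
#' per-cell sub-seed derived from the master seed, and binds the one-row
#' summaries into a table. The default configuration is the canonical
#' design: 3 input functions x 10 three-point schedules from
#' {24, 48, 96, 144, 192} h x rKi {1, 5, 20} 10^-3 /h x
#' rVT {0.1, 0.2, 0.5} x noise {5, 10, 15}% = 810 conditions of 1000
#' repetitions each.
#'
#' @param config A configuration list as returned by [default_config()] or
#'   [load_config()].
#' @param progress Print a progress line per input function.
#' @return A data frame with one [run_condition()] summary row per cell.
#' @examples
#' cfg <- default_config()
#' cfg$rki <- 5e-3; cfg$rvt <- 0.2; cfg$noise <- 0.05; cfg$n_reps <- 50
#' cfg$fixtures <- "pertuzumab-like"
#' dim(run_grid(cfg))  # 10 schedules x 1 x 1 x 1
#' @export
run_grid <- function(config = default_config(), progress = FALSE) {
  config <- validate_config(config)
  ifns <- resolve_input_functions(config)
  schedules <- enumerate_schedules(config$candidate_times,
                                   config$schedule_size,
                                   config$require_time)
  if (length(schedules) == 0L) {
    stop("no schedules satisfy the configuration", call. = FALSE)
  }
  rows <- vector("list",
                 length(ifns) * length(schedules) * length(config$rki) *
                   length(config$rvt) * length(config$noise))
  i <- 0L
  for (lab in names(ifns)) {
    if (progress) message("input function: ", lab)
    for (sch in schedules) {
      for (ki in config$rki) for (vt in config$rvt) for (nz in config$noise) {
        seed <- condition_seed(
          config$seed,
          condition_descriptor(lab, sch$imaging_times, ki, vt, nz))
        cond <- condition(ifns[[lab]], sch, ki, vt, nz,
                          n_reps = config$n_reps, seed = seed,
                          half_life = config$half_life)
        i <- i + 1L
        rows[[i]] <- run_condition(cond)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a grid summary table to CSV
#'
#' @param summary A data frame from [run_grid()] or [run_condition()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
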