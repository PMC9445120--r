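base_cond <- function(noise0 = 0.05, n_reps = 200, seed = 11,
                      ki = 5e-3, vt = 0.2,
                      ifn = input_function_library("trastuzumab-like"),
                      times = c(24, 48, 96)) {
  condition(ifn, sampling_schedule(times), ki, vt, noise0,
            n_reps = n_reps, seed = seed)
}

test_that("a zero-deviate repetition gives the pure trapezoid-bias estimate", {
  cond <- base_cond()
  est <- run_repetition(cond, z = c(0, 0, 0))
  # identical to fitting the noise-free curves directly
  sch <- cond$schedule
  cp <- predict(cond$ifn, sch$plasma_times)
  ct <- simulate_tac(cond$ifn, cond$ki, cond$vt, sch$imaging_times)
  f <- patlak(patlak_coordinates(sch$plasma_times, cp, sch$imaging_times, ct))
  expect_equal(unname(est), unname(coef(f)), tolerance = 1e-13)
  expect_lt(est[["ki_hat"]], cond$ki)

  # noise0 = 0 makes every repetition deterministic
  cond0 <- base_cond(noise0 = 0)
  expect_equal(run_repetition(cond0, z = c(3, -2, 1)),
               run_repetition(cond0, z = c(0, 0, 0)))
})

test_that("the vectorised condition sweep equals repeated single runs", {
  cond <- base_cond(n_reps = 5, seed = 99)
  out <- run_condition(cond)
  set.seed(99)
  z <- matrix(rnorm(5 * 3), nrow = 5, ncol = 3, byrow = TRUE)
  singles <- t(vapply(1:5, function(i) run_repetition(cond, z[i, ]),
                      c(ki_hat = 0, vt_hat = 0)))
  expect_equal(out$mean_ki, mean(singles[, "ki_hat"]), tolerance = 1e-12)
  expect_equal(out$mean_vt, mean(singles[, "vt_hat"]), tolerance = 1e-12)
  expect_equal(out$sd_ki, sd(singles[, "ki_hat"]), tolerance = 1e-10)
})

test_that("condition summaries satisfy their defining identities", {
  out <- run_condition(base_cond())
  expect_equal(out$bias_ki_pct,
               100 * (out$mean_ki - out$rki_per_h) / out$rki_per_h)
  expect_equal(out$variability_vt_pct, 100 * out$sd_vt / out$rvt)
  expect_equal(out$n_failed, 0)
  expect_equal(out$noise_pct, 5)

  # zero noise: sd and variability collapse, bias is the trapezoid bias
  out0 <- run_condition(base_cond(noise0 = 0))
  expect_equal(out0$sd_ki, 0)
  expect_equal(out0$variability_ki_pct, 0)
  expect_equal(out0$mean_ki, out0$ki_noise_free)
  expect_lt(out0$bias_ki_pct, 0)
})

test_that("identical seeds reproduce and the MC mean obeys the CLT bound", {
  a <- run_condition(base_cond(seed = 123))
  b <- run_condition(base_cond(seed = 123))
  expect_identical(a, b)
  c <- run_condition(base_cond(seed = 124))
  expect_false(isTRUE(all.equal(a$mean_ki, c$mean_ki)))

  # noise is mean-zero and the estimator linear: MC mean near the z = 0 value
  big <- run_condition(base_cond(n_reps = 2000, seed = 5))
  expect_lt(abs(big$mean_ki - big$ki_noise_free),
            3 * big$sd_ki / sqrt(big$n_reps))
  expect_lt(abs(big$mean_vt - big$vt_noise_free),
            3 * big$sd_vt / sqrt(big$n_reps))
})

test_that("variability scales linearly with the noise level", {
  # common random numbers isolate the scaling law: same seed, 3x noise0
  lo <- run_condition(base_cond(noise0 = 0.05, seed = 77, n_reps = 1000))
  hi <- run_condition(base_cond(noise0 = 0.15, seed = 77, n_reps = 1000))
  expect_equal(hi$sd_ki / lo$sd_ki, 3, tolerance = 1e-6)
  expect_equal(hi$sd_vt / lo$sd_vt, 3, tolerance = 1e-6)
  # under common deviates the MC mean deviates from the noise-free value
  # in proportion to the noise level as well
  expect_equal(hi$mean_ki - hi$ki_noise_free,
               3 * (lo$mean_ki - lo$ki_noise_free), tolerance = 1e-9)
})

test_that("per-condition sub-seeds are stable, valid and descriptor-keyed", {
  d1 <- condition_descriptor("x", c(24, 48, 96), 1e-3, 0.2, 0.05)
  d2 <- condition_descriptor("x", c(24, 48, 96), 1e-3, 0.2, 0.10)
  expect_identical(condition_seed(1, d1), condition_seed(1, d1))
  expect_false(condition_seed(1, d1) == condition_seed(1, d2))
  expect_false(condition_seed(1, d1) == condition_seed(2, d1))
  seeds <- vapply(1:500, function(i) condition_seed(i, d1), integer(1))
  expect_true(all(seeds >= 1 & seeds < 2^31 - 1))
})

test_that("run_grid crosses the axes and is reproducible per master seed", {
  cfg <- default_config(n_reps = 20, seed = 4)
  cfg$fixtures <- "pertuzumab-like"
  cfg$rki <- c(1e-3, 5e-3); cfg$rvt <- 0.2; cfg$noise <- c(0.05, 0.15)
  g <- run_grid(cfg)
  expect_equal(nrow(g), 10 * 2 * 1 * 2)
  expect_setequal(unique(g$rki_per_h), c(1e-3, 5e-3))
  expect_identical(g, run_grid(cfg))

  cfg$require_time <- 24
  expect_equal(nrow(run_grid(cfg)), 6 * 2 * 1 * 2)

  # adding axis values never perturbs existing cells
  cfg2 <- cfg
  cfg2$rvt <- c(0.2, 0.5)
  g1 <- run_grid(cfg)
  g2 <- run_grid(cfg2)
  shared <- g2[g2$rvt == 0.2, ]
  rownames(shared) <- rownames(g1) <- NULL
  expect_equal(shared, g1)
})

test_that("grid summaries round-trip through CSV", {
  cfg <- default_config(n_reps = 10, seed = 2)
  cfg$fixtures <- "huJ591-like"
  cfg$rki <- 5e-3; cfg$rvt <- 0.2; cfg$noise <- 0.05
  cfg$require_time <- 24
  g <- run_grid(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_summary(g, path)
  back <- utils::read.csv(path)
  expect_equal(back$bias_ki_pct, g$bias_ki_pct)
  expect_equal(names(back), names(g))
})
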