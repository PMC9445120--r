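test_that("sparse trapezoidal AUC is exact for polynomials of degree <= 1", {
  expect_equal(trapezoid_auc(c(0, 24), c(3, 3), 24), 72)
  tt <- c(0, 24, 48, 96)
  lin <- 10 - 0.05 * tt
  expect_equal(trapezoid_auc(tt, lin, 96), 10 * 96 - 0.05 * 96^2 / 2)
  expect_equal(trapezoid_auc(tt, lin, 0), 0)
  expect_error(trapezoid_auc(tt, lin, 30), "no interpolation")
  expect_error(trapezoid_auc(c(24, 48), c(1, 1), 48), "t = 0")
})

test_that("trapezoidal AUC dominates the analytic AUC and refines toward it", {
  for (nm in fixture_names) {
    ifn <- input_function_library(nm)
    tt <- c(0, candidate_times)
    cp <- predict(ifn, tt)
    for (upto in candidate_times) {
      expect_gt(trapezoid_auc(tt, cp, upto), auc(ifn, upto))
    }
    # adding intermediate samples shrinks the trapezoid toward the integral
    coarse <- c(0, 96)
    finer <- c(0, 48, 96)
    finest <- c(0, 24, 48, 72, 96)
    aucs <- vapply(list(coarse, finer, finest), function(s)
      trapezoid_auc(s, predict(ifn, s), 96), numeric(1))
    expect_true(all(diff(aucs) < 0))
    expect_gt(aucs[3], auc(ifn, 96))
  }
})

test_that("Patlak coordinates compose plasma, tissue and the sparse AUC", {
  ifn <- input_function_library("pertuzumab-like")
  tt <- c(0, 24, 48, 96)
  cp <- predict(ifn, tt)

  # tissue proportional to plasma puts every y at vt
  co <- patlak_coordinates(tt, cp, tt[-1], 0.3 * cp[-1])
  expect_equal(co$y, rep(0.3, 3))
  expect_equal(nrow(co), 3) # the t = 0 sample is not a regression point
  expect_true(all(diff(co$x) > 0))

  # noise-free reference scenario: x and y from explicit composition
  ct <- simulate_tac(ifn, 1e-3, 0.2, tt[-1])
  co2 <- patlak_coordinates(tt, cp, tt[-1], ct)
  expect_equal(co2$x,
               vapply(tt[-1], function(u) trapezoid_auc(tt, cp, u),
                      numeric(1)) / cp[-1])
  expect_equal(co2$y, ct / cp[-1])

  expect_error(patlak_coordinates(tt, c(1, 0, 1, 1), tt[-1], ct), "zero")
  expect_error(patlak_coordinates(tt, cp, c(24, 60), c(1, 1)),
               "plasma sample")
})

test_that("the Patlak OLS fit is exact on collinear input", {
  x <- c(30, 60, 90)
  f <- patlak(x, 0.005 * x + 0.2)
  expect_equal(coef(f), c(Ki = 0.005, VT = 0.2))
  expect_equal(unname(residuals(f)), rep(0, 3))

  two <- patlak(c(10, 20), c(1, 3))
  expect_equal(coef(two), c(Ki = 0.2, VT = -1))

  df <- data.frame(x = x, y = 2 * x - 5)
  expect_equal(coef(patlak(df)), c(Ki = 2, VT = -5))

  expect_error(patlak(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(patlak(3, 1), "at least 2")
})

test_that("Patlak OLS matches lm on noisy coordinates", {
  set.seed(9)
  for (i in 1:10) {
    x <- sort(runif(5, 10, 120))
    y <- 0.004 * x + 0.3 + rnorm(5, sd = 0.05)
    f <- patlak(x, y)
    ref <- unname(coef(lm(y ~ x)))
    expect_equal(unname(coef(f)), rev(ref), tolerance = 1e-12)
    s <- summary(f)
    lm_se <- summary(lm(y ~ x))$coefficients[, "Std. Error"]
    expect_equal(unname(s$coefficients[, "Std. Error"]),
                 unname(rev(lm_se)), tolerance = 1e-10)
  }
})

test_that("estimation self-inverts exactly with the analytic AUC", {
  for (nm in fixture_names) {
    ifn <- input_function_library(nm)
    for (sch in enumerate_schedules()) {
      it <- sch$imaging_times
      cp <- predict(ifn, it)
      x_analytic <- auc(ifn, it) / cp
      for (r in seq_len(nrow(ref_grid))) {
        y <- simulate_tac(ifn, ref_grid$ki[r], ref_grid$vt[r], it) / cp
        f <- patlak(x_analytic, y)
        expect_equal(coef(f)[["Ki"]], ref_grid$ki[r], tolerance = 1e-10)
        expect_equal(coef(f)[["VT"]], ref_grid$vt[r], tolerance = 1e-10)
      }
    }
  }
})

test_that("the sparse trapezoidal AUC always depresses the Ki estimate", {
  for (nm in fixture_names) {
    ifn <- input_function_library(nm)
    for (sch in enumerate_schedules()) {
      pt <- sch$plasma_times; it <- sch$imaging_times
      cp_all <- predict(ifn, pt)
      for (r in seq_len(nrow(ref_grid))) {
        ct <- simulate_tac(ifn, ref_grid$ki[r], ref_grid$vt[r], it)
        f <- patlak(patlak_coordinates(pt, cp_all, it, ct))
        expect_lt(coef(f)[["Ki"]], ref_grid$ki[r])
      }
    }
  }
})

test_that("patlak methods print and plot without error", {
  f <- patlak(c(30, 60, 90), c(0.35, 0.51, 0.62))
  expect_output(print(f), "Ki")
  expect_output(print(summary(f)), "R-squared")
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, 100), coef(f)[["Ki"]] * 100 + coef(f)[["VT"]])
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(f))
})
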