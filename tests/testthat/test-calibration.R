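test_that("exact quadratic data is fitted with zero residuals", {
  sc <- exact_scale()
  expect_equal(sc$coefficients, c(0.5, 0.1, 0.01), tolerance = 1e-9)
  expect_length(sc$fitted_vector, 101L)
  expect_equal(brightness_to_luminance(sc, 100), 110.5, tolerance = 1e-9)
  expect_equal(brightness_to_luminance(sc, 50), 30.5, tolerance = 1e-9)
  expect_equal(brightness_to_luminance(sc, 12), 3.14, tolerance = 1e-9)
  expect_equal(sc$chi2, 0, tolerance = 1e-12)
  expect_equal(sc$p_value, 1)
  expect_equal(sc$residual_sd, 0, tolerance = 1e-12)
})

test_that("constant measurements give a constant fitted vector", {
  m <- data.frame(brightness_pct = seq(0, 100, 20), luminance = rep(5, 6))
  sc <- fit_luminance_scale(m)
  expect_equal(sc$fitted_vector, rep(5, 101), tolerance = 1e-9)
})

test_that("fit matches an independent normal-equations least-squares oracle", {
  set.seed(7)
  b <- seq(0, 100, 20)
  for (rep in 1:5) {
    # noisy data from a cubic: quadratic fit is a genuine approximation
    l <- 2 + 0.05 * b + 0.002 * b^2 + 1e-5 * b^3 + rnorm(6, sd = 0.5)
    l <- pmax(l, 0.01)
    sc <- fit_luminance_scale(data.frame(brightness_pct = b, luminance = l))
    expect_equal(sc$coefficients, ls_quadratic_oracle(b, l),
                 tolerance = 1e-9)
  }
})

test_that("degree <= 2 polynomial coefficients are recovered exactly", {
  set.seed(11)
  for (rep in 1:10) {
    co <- c(runif(1, 0.1, 5), runif(1, 0, 1), runif(1, 0, 0.02))
    sc <- fit_luminance_scale(quad_measurements(co[1], co[2], co[3]))
    expect_equal(sc$coefficients, co, tolerance = 1e-9)
  }
})

test_that("invalid calibration input is rejected", {
  m <- quad_measurements()
  expect_error(fit_luminance_scale(m[-1, ]), "six measurements")
  m2 <- m; m2$brightness_pct[2] <- 0
  expect_error(fit_luminance_scale(m2), "six measurements")
  m3 <- m; m3$luminance[1] <- -1
  expect_error(fit_luminance_scale(m3), "non-negative")
  m4 <- m; m4$brightness_pct[6] <- 90
  expect_error(fit_luminance_scale(m4), "six measurements")
})

test_that("negative fitted luminance is clamped to zero with a warning", {
  # quadratic positive at every measured level but dipping below zero
  # between brightness 0 and 20
  expect_warning(sc <- fit_luminance_scale(quad_measurements(1.5, -0.4,
                                                             0.02)),
                 "clamped")
  expect_true(all(sc$fitted_vector >= 0))
  expect_equal(sc$fitted_vector[11], 0) # f(10) = -0.5, clamped
})

test_that("goodness of fit reproduces printed chi-squared p-values at df = 5", {
  expect_equal(round(pchisq(1.63, 5, lower.tail = FALSE), 3), 0.898)
  p1 <- goodness_of_fit(c(1, 2, 3, 4, 5, 6.9), c(1, 2, 3, 4, 5, 6.9))
  expect_equal(p1$p_value, 1)
  # p_value path equals the analytic survival function used directly
  g <- goodness_of_fit(c(1.2, 2.3, 2.8, 4.4, 5.1, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(g$p_value, pchisq(g$chi2, 5, lower.tail = FALSE))
  expect_equal(g$residual_sd, sd(c(0.2, 0.3, -0.2, 0.4, 0.1, 0)))
})

test_that("chi-squared p-value matches a numeric-integration oracle and is
           decreasing in chi2", {
  dens <- function(x) x^(5 / 2 - 1) * exp(-x / 2) / (2^(5 / 2) * gamma(5 / 2))
  for (chi2 in c(0.5, 1.63, 2.12, 5, 11)) {
    oracle <- integrate(dens, chi2, Inf, rel.tol = 1e-10)$value
    g <- goodness_of_fit(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
    expect_equal(pchisq(chi2, 5, lower.tail = FALSE), oracle,
                 tolerance = 1e-6)
  }
  chis <- seq(0, 20, by = 0.5)
  ps <- pchisq(chis, 5, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("goodness of fit rejects non-positive fitted values", {
  expect_error(goodness_of_fit(1:6, c(0, 2, 3, 4, 5, 6)), "degenerate")
})

test_that("brightness lookup enforces the integer 0..100 domain", {
  sc <- exact_scale()
  expect_error(brightness_to_luminance(sc, 101), "0..100")
  expect_error(brightness_to_luminance(sc, -1), "0..100")
  expect_error(brightness_to_luminance(sc, 12.5), "0..100")
  expect_equal(eval_luminance(sc, 12.5), 0.5 + 0.1 * 12.5 + 0.01 * 12.5^2)
})

test_that("decibel arithmetic matches its definition and inverts exactly", {
  expect_equal(luminance_to_db(10, 10), 0)
  expect_equal(db_to_luminance(0, 7), 7)
  expect_error(luminance_to_db(0, 10), "positive")
  expect_error(luminance_to_db(11, 10), "exceed")
  expect_error(db_to_luminance(-1, 10), "non-negative")
  set.seed(3)
  for (rep in 1:50) {
    l_max <- runif(1, 1, 400)
    l <- runif(1, 1e-4, 1) * l_max
    db <- luminance_to_db(l, l_max)
    expect_equal(db_to_luminance(db, l_max), l, tolerance = 1e-9)
  }
  # strictly decreasing in l_t
  l_t <- seq(0.5, 100, length.out = 40)
  expect_true(all(diff(luminance_to_db(l_t, 100)) < 0))
})

test_that("calibration CSV round-trips through the documented header", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- quad_measurements()
  write.csv(data.frame(brightness_pct = m$brightness_pct,
                       luminance_cd_m2 = m$luminance), path,
            row.names = FALSE)
  expect_equal(read_calibration_csv(path)$luminance, m$luminance)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_calibration_csv(bad), "header")
})
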