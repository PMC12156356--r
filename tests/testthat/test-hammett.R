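# Hammett model: lookups, closed-form OLS against independent oracles,
# scale ranking, prediction, parameter recovery.

test_that("sigma lookup returns tabulated constants and helpful errors", {
  expect_equal(sigma_lookup("H", "sigma_p"), 0)
  expect_equal(sigma_lookup("H", "sigma_I"), 0)
  expect_equal(sigma_lookup("NO2", "sigma_p"), 0.78)
  expect_equal(sigma_lookup(c("Me", "CN"), "sigma_p"), c(-0.17, 0.66))
  expect_error(sigma_lookup("XYZ", "sigma_p"), "available")
  expect_error(sigma_lookup("H", "sigma_zz"), "unknown scale")
})

test_that("a perfect line is fitted exactly", {
  d <- data.frame(substituent = c("H", "Me", "Cl", "NO2"),
                  sigma_p = c(0, -0.17, 0.23, 0.78))
  d$delta_omega <- 0.9 + 0.8 * d$sigma_p
  f <- hammett_fit(substituent_series("lin", d))
  expect_equal(f$slope, 0.8, tolerance = 1e-12)
  expect_equal(f$intercept, 0.9, tolerance = 1e-12)
  expect_equal(abs(f$pearson_r), 1, tolerance = 1e-12)
  expect_equal(unname(coef(f)), c(0.9, 0.8), tolerance = 1e-12)
  # refit reproducibility
  f2 <- hammett_fit(substituent_series("lin", d))
  expect_identical(coef(f), coef(f2))
})

test_that("closed-form OLS agrees with lm() and the long-hand oracle", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- round(runif(n, -0.9, 0.9), 3)
    y <- 0.3 + runif(1, -1, 1) * x + rnorm(n, 0, 0.2)
    d <- data.frame(substituent = paste0("s", seq_len(n)),
                    sigma_p = x, delta_omega = y)
    f <- hammett_fit(substituent_series("rnd", d, fill_sigma = FALSE))
    ref_lm <- lm(y ~ x)
    expect_equal(f$slope, unname(coef(ref_lm)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(ref_lm)[1]), tolerance = 1e-10)
    expect_equal(f$pearson_r, cor(x, y), tolerance = 1e-10)
    expect_equal(f$se_slope, summary(ref_lm)$coefficients[2, 2],
                 tolerance = 1e-10)
    o <- naive_ols(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-12)
    expect_equal(f$pearson_r, o$r, tolerance = 1e-12)
  }
})

test_that("R is invariant under affine rescaling of delta-omega", {
  s <- gen_hammett_series(0.8, 0.9, noise_sd = 0.05, seed = 4)
  f <- hammett_fit(s)
  d2 <- s$data
  d2$delta_omega <- 3.1 * d2$delta_omega - 0.4
  f2 <- hammett_fit(substituent_series("scaled", d2))
  expect_equal(f2$pearson_r, f$pearson_r, tolerance = 1e-12)
  expect_equal(f2$slope, 3.1 * f$slope, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(substituent = c("a", "b"), sigma_p = c(0, 1),
                  delta_omega = c(1, 2))
  expect_error(hammett_fit(substituent_series("tiny", d, fill_sigma = FALSE)),
               "at least 3")
  d3 <- data.frame(substituent = c("a", "b", "c"), sigma_p = c(0.2, 0.2, 0.2),
                   delta_omega = c(1, 2, 3))
  expect_error(hammett_fit(substituent_series("flat", d3, fill_sigma = FALSE)),
               "degenerate")
  # missing sigmas drop listwise
  d4 <- data.frame(substituent = letters[1:5], sigma_p = c(0, NA, 0.3, 0.6, 0.9),
                   delta_omega = c(1, 2, 1.2, 1.5, 1.7))
  f4 <- hammett_fit(substituent_series("na", d4, fill_sigma = FALSE))
  expect_equal(f4$n_points, 4L)
})

test_that("compare_scales ranks by |R| with the constructed scale on top", {
  subs <- fixture_substituents()
  d <- data.frame(substituent = subs)
  d$sigma_p <- sigma_lookup(subs, "sigma_p")
  d$sigma_I <- sigma_lookup(subs, "sigma_I")
  set.seed(8)
  d$delta_omega <- 0.9 + 0.8 * d$sigma_p + rnorm(8, 0, 0.02)
  cmp <- compare_scales(substituent_series("cmp", d, fill_sigma = TRUE))
  expect_identical(cmp$scale[1], "sigma_p")
  expect_true(all(diff(cmp$abs_r) <= 1e-12))
  # identical data under two scales ties and is flagged
  d$sigma_I <- d$sigma_p
  cmp2 <- compare_scales(substituent_series("tie", d, fill_sigma = FALSE),
                         scales = c("sigma_p", "sigma_I"))
  expect_true(all(cmp2$tie))
})

test_that("prediction composes the line with the polarity rule", {
  d <- data.frame(substituent = c("H", "Me", "NO2"),
                  sigma_p = c(0, -0.17, 0.78))
  d$delta_omega <- 0.9 + 0.8 * d$sigma_p
  f <- hammett_fit(substituent_series("p", d))
  expect_equal(predict(f, 0), 0.9, tolerance = 1e-12)
  pr <- predict_delta_omega(f, c(0.5, 0.1))
  expect_equal(pr$delta_omega, c(1.3, 0.98), tolerance = 1e-10)
  expect_identical(pr$polarity, c("polar", "nonpolar"))
  # labels are looked up on the fit's scale
  expect_equal(predict(f, "NO2"), 0.9 + 0.8 * 0.78, tolerance = 1e-10)
})

test_that("the fitted slope recovers the truth over seeded replicates", {
  slopes <- numeric(200)
  cover <- logical(200)
  for (s in 1:200) {
    ser <- gen_hammett_series(0.8, 0.9, noise_sd = 0.05, seed = s)
    f <- hammett_fit(ser)
    slopes[s] <- f$slope
    cover[s] <- abs(f$slope - 0.8) <= 2 * f$se_slope
  }
  expect_lt(abs(mean(slopes) - 0.8) / 0.8, 0.02)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
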