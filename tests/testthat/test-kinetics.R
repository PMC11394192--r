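test_that("isothermal rate fits recover exact decay parameters", {
  t <- seq(0, 90, by = 15)
  r1 <- suppressWarnings(fit_rate(t, 100 * exp(-0.02 * t), order = "first"))
  expect_equal(r1$k, 0.02, tolerance = 1e-12)
  expect_equal(r1$intercept, 100, tolerance = 1e-9)
  expect_equal(r1$r2, 1, tolerance = 1e-12)

  r0 <- suppressWarnings(fit_rate(t, 9 - 0.05 * t, order = "zero"))
  expect_equal(r0$k, 0.05, tolerance = 1e-12)
  expect_equal(r0$intercept, 9, tolerance = 1e-12)

  expect_error(fit_rate(c(0, 10), c(1, 2), "first"), "3 points")
  expect_error(fit_rate(t, c(-1, rep(1, 6)), "first"), "positive")
  set.seed(3)
  expect_warning(fit_rate(t, 5 + 0.01 * t + rnorm(7, sd = 0.01), "zero"),
                 "no degradation")
})

test_that("median fitted rate is unbiased under multiplicative noise", {
  t7 <- seq(0, 90, by = 15)
  khat <- vapply(1:500, function(s) {
    set.seed(s)
    tt <- rep(t7, each = 3)
    v <- 100 * exp(-0.01 * tt) * exp(rnorm(length(tt), sd = 0.05))
    agg <- aggregate(v, list(tt), mean)
    fit_rate(agg[[1]], agg[[2]], "first")$k
  }, numeric(1))
  expect_lt(abs(median(khat) - 0.01) / 0.01, 0.1)
})

test_that("Arrhenius fits match the two-point closed form and round-trip", {
  # closed form: E_a = R log(k2/k1) / (1/T1 - 1/T2)
  m <- fit_arrhenius(data.frame(temperature = c(-23, -5), k = c(0.002, 0.02)))
  expect_equal(m$E_a / 1000, 71.34, tolerance = 0.005)
  expect_equal(m$k_ref, 0.00392, tolerance = 1e-3)

  # equal rates everywhere: no temperature dependence
  m0 <- fit_arrhenius(data.frame(temperature = c(-20, -10, -5), k = rep(0.01, 3)))
  expect_equal(m0$E_a, 0, tolerance = 1e-8)
  expect_equal(m0$k_ref, 0.01, tolerance = 1e-10)

  # noiseless round trip at the four study temperatures recovers the preset
  gen <- preset_model("vitamin_c", "od")
  rates <- data.frame(temperature = c(-5, -8, -14, -23),
                      k = rate_at(gen, c(-5, -8, -14, -23)))
  rec <- fit_arrhenius(rates)
  expect_lt(abs(rec$E_a - gen$E_a) / gen$E_a, 1e-3)
  expect_lt(abs(rec$k_ref - gen$k_ref) / gen$k_ref, 1e-3)

  expect_error(fit_arrhenius(data.frame(temperature = -5, k = 0.01)),
               "insufficient")
  r1 <- suppressWarnings(fit_rate(0:5, 10 * exp(-0.1 * (0:5)), "first", temperature = -5))
  r2 <- suppressWarnings(fit_rate(0:5, 9 - 0.2 * (0:5), "zero", temperature = -15))
  expect_error(fit_arrhenius(list(r1, r2)), "mixed")
})

test_that("rates increase and shelf lives decrease with temperature", {
  m <- arrhenius_model(k_ref = 0.0033, E_a = 88800, order = "first",
                       initial_value = 100, limit_value = 50)
  expect_equal(rate_at(m, -18), 0.0033)
  expect_equal(rate_at(m, -5), 0.0251, tolerance = 1e-3)
  expect_equal(rate_at(m, -23), 0.00143, tolerance = 1e-2)

  grid <- seq(-30, -2, by = 1)
  expect_true(all(diff(rate_at(m, grid)) > 0))
  expect_true(all(diff(shelf_life(m, grid)) < 0))

  expect_equal(shelf_life(m, -18, loss_fraction = 0.5), log(2) / 0.0033,
               tolerance = 1e-10)
  mz <- arrhenius_model(k_ref = 0.009, E_a = 57100, order = "zero",
                        initial_value = 9, limit_value = 4)
  expect_equal(shelf_life(mz, -18), 5 / 0.009, tolerance = 1e-10)
  expect_error(shelf_life(m, -18, initial = 50, limit = 50), "below the initial")
  expect_error(shelf_life(mz, -18, loss_fraction = 0.5), "first-order")
})

test_that("temperature profiles concatenate cycles and validate durations", {
  p <- make_cycle_profile(c(-12, -5, -8), c(24, 24, 24), repeats = 3)
  expect_equal(nrow(p), 9)
  expect_equal(attr(p, "t_tot_h"), 216)
  expect_equal(p$temperature, rep(c(-12, -5, -8), 3))
  expect_error(temperature_profile(-5, 0), "positive")
  expect_error(make_cycle_profile(-5, 24, repeats = 0), "repeats")
})

test_that("effective temperature behaves like the Arrhenius-mean temperature", {
  m <- arrhenius_model(k_ref = 0.0033, E_a = 88800, order = "first")

  # constant profile: T_eff is that temperature
  expect_equal(effective_temperature(temperature_profile(-8, 48), m), -8,
               tolerance = 1e-10)

  # three-step day cycle: direct evaluation of the closed form
  cyc <- temperature_profile(c(-12, -5, -8), c(24, 24, 24))
  expect_equal(effective_temperature(cyc, m), -7.765, tolerance = 1e-3)

  # repeating the cycle leaves T_eff unchanged (time-weight invariance)
  p3 <- make_cycle_profile(c(-12, -5, -8), c(24, 24, 24), repeats = 3)
  expect_equal(effective_temperature(p3, m), effective_temperature(cyc, m),
               tolerance = 1e-12)

  # bracketed by the segment range, warmer than the arithmetic mean,
  # and monotone increasing in E_a
  teffs <- vapply(seq(10, 300, by = 10) * 1000, function(ea)
    effective_temperature(p3, ea), numeric(1))
  expect_true(all(teffs > -12 & teffs < -5))
  expect_true(all(teffs > mean(c(-12, -5, -8))))
  expect_true(all(diff(teffs) > 0))

  # E_a = 0 limit falls back to the harmonic mean with a warning
  expect_warning(t0 <- effective_temperature(cyc, arrhenius_model(1, 0)),
                 "harmonic")
  expect_equal(t0, 1 / mean(1 / (c(-12, -5, -8) + 273.15)) - 273.15,
               tolerance = 1e-10)
})

test_that("non-isothermal prediction integrates segments in closed form", {
  m <- arrhenius_model(k_ref = 0.0033, E_a = 88800, order = "first",
                       initial_value = 100, limit_value = 50)

  # constant profile equals the isothermal closed form
  p <- temperature_profile(rep(-8, 4), rep(24, 4))
  tr <- predict_nonisothermal(m, p)
  expect_equal(tail(tr$value, 1), 100 * exp(-rate_at(m, -8) * 4),
               tolerance = 1e-12)

  # hand-computed two-segment first-order decay, one day per segment
  m2 <- fit_arrhenius(data.frame(temperature = c(-12, -5), k = c(0.01, 0.03)))
  p2 <- temperature_profile(c(-12, -5), c(24, 24))
  tr2 <- predict_nonisothermal(m2, p2, initial = 1)
  expect_equal(tail(tr2$value, 1), exp(-0.04), tolerance = 1e-10)

  # any profile: end value equals the constant-T_eff run of equal duration
  p3 <- make_cycle_profile(c(-12, -5, -8), c(24, 24, 24), repeats = 3)
  teff <- effective_temperature(p3, m)
  end <- tail(predict_nonisothermal(m, p3)$value, 1)
  expect_equal(end, 100 * exp(-rate_at(m, teff) * 9), tolerance = 1e-10)

  mz <- arrhenius_model(k_ref = 0.017, E_a = 56580, order = "zero",
                        initial_value = 7.1, limit_value = 4)
  endz <- tail(predict_nonisothermal(mz, p3)$value, 1)
  teffz <- effective_temperature(p3, mz)
  expect_equal(endz, 7.1 - rate_at(mz, teffz) * 9, tolerance = 1e-10)

  # zero-order predictions below the limit are flagged, not floored
  long <- temperature_profile(-5, 24 * 60)
  trz <- predict_nonisothermal(mz, long)
  expect_true(attr(trz, "below_limit"))
  expect_lt(tail(trz$value, 1), 4)
})

test_that("relative error reports signed percent with the 20% acceptance rule", {
  expect_equal(as.numeric(relative_error(0.01, 0.01)), 0)
  expect_true(attr(relative_error(0.01, 0.01), "accepted"))
  re <- relative_error(0.010, 0.012)
  expect_equal(as.numeric(re), -20, tolerance = 1e-10)
  expect_true(attr(re, "accepted"))
  re2 <- relative_error(0.010, 0.015)
  expect_equal(as.numeric(re2), -50, tolerance = 1e-10)
  expect_false(attr(re2, "accepted"))
  expect_error(relative_error(0, 0.01), "nonzero")
})
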