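test_that("individual desirability ramps behave as Derringer linear ramps", {
  cr <- criterion("y", "minimize", bound_low = 2, bound_high = 10)
  expect_equal(individual_desirability(2, cr), 1)
  expect_equal(individual_desirability(10, cr), 0)
  expect_equal(individual_desirability(6, cr), 0.5)
  expect_equal(individual_desirability(c(0, 12), cr), c(1, 0))  # clamped

  cx <- criterion("y", "maximize", bound_low = 0, bound_high = 4)
  expect_equal(individual_desirability(c(0, 1, 4), cx), c(0, 0.25, 1))

  # upper_bound is a soft cap: full desirability at or below the cap
  cu <- criterion("y", "upper_bound", bound_low = 5, bound_high = 9)
  expect_equal(individual_desirability(c(3, 5, 7, 9), cu), c(1, 1, 0.5, 0))

  ct <- criterion("y", "target", bound_low = 0, bound_high = 10, target = 4)
  expect_equal(individual_desirability(c(0, 2, 4, 7, 10), ct),
               c(0, 0.5, 1, 0.5, 0))

  # weights act as ramp exponents: heavier weight lowers interior d
  cw <- criterion("y", "minimize", bound_low = 2, bound_high = 10, weight = 2)
  expect_equal(individual_desirability(6, cw), 0.25)
  for (y in c(3, 5, 9.5)) {
    d1 <- individual_desirability(y, cr)
    d2 <- individual_desirability(y, cw)
    expect_lt(d2, d1)
  }

  expect_error(individual_desirability(NaN, cr), "finite")
  expect_error(criterion("y", "minimize", bound_low = 5, bound_high = 5),
               "strictly less")
  expect_error(criterion("y", "minimize", weight = 0), "positive")
})

test_that("composite desirability is the geometric mean with annihilating zero", {
  expect_equal(composite_desirability(c(1, 1, 1)), 1)
  expect_equal(composite_desirability(c(0.25, 1)), 0.5)
  expect_equal(composite_desirability(c(0.3, 0, 0.9)), 0)
  # invariant to ordering
  set.seed(9)
  d <- runif(5)
  expect_equal(composite_desirability(d), composite_desirability(rev(d)))
  # D = 1 iff all d = 1; D <= max(d)
  expect_lt(composite_desirability(c(1, 1, 0.99)), 1)
  expect_lte(composite_desirability(d), max(d))
  expect_error(composite_desirability(numeric(0)), "no desirabilities")
  expect_error(composite_desirability(c(0.5, 1.2)), "0, 1")
})

test_that("optimizer finds the analytic minimum of a single convex surface", {
  # convex coded-unit quadratic with an interior stationary point
  a <- c(1, 0.1, -0.2, 0.05, 1, 0.8, 1.2, 0.1, -0.05, 0.02)
  Q <- matrix(c(2 * a[5], a[8], a[9],
                a[8], 2 * a[6], a[10],
                a[9], a[10], 2 * a[7]), 3, 3)
  x_star <- solve(Q, -a[2:4])           # closed-form stationary point
  m <- quadratic_model(a, ref_space, response = "y", form = "coded")
  y_star <- predict(m, x_star, units = "coded")

  res <- optimize_desirability(
    list(y = m),
    list(criterion("y", "minimize", bound_low = y_star - 0.1)),
    grid_n = 21
  )
  expect_equal(unname(res$optimum_coded), x_star, tolerance = 0.01)
  expect_equal(unname(res$predicted["y"]), y_star, tolerance = 1e-4)
})

test_that("optimizer is deterministic and matches a brute-force grid oracle", {
  models <- od_reference_models(ref_space)[c("aw", "WL", "dE")]
  res1 <- optimize_desirability(models, od_default_criteria(), grid_n = 21)
  res2 <- optimize_desirability(models, od_default_criteria(), grid_n = 21)
  expect_identical(res1, res2)

  # independent oracle: exhaustive 101^3 grid evaluated with hand-written
  # polynomial and ramp arithmetic, using the same resolved ramp bounds
  co <- od_surface_coefficients()
  g <- expand.grid(T = seq(25, 45, length.out = 101),
                   t = seq(30, 90, length.out = 101),
                   C = seq(50, 70, length.out = 101))
  surf <- sapply(c("aw", "WL", "dE"), function(r)
    oracle_quad(co[, r], g$T, g$t, g$C))
  bounds <- lapply(res1$criteria, function(cr) c(cr$bound_low, cr$bound_high))
  names(bounds) <- sapply(res1$criteria, `[[`, "response")
  dmat <- cbind(
    aw = pmin(1, pmax(0, (bounds$aw[2] - surf[, "aw"]) / diff(bounds$aw))),
    WL = pmin(1, pmax(0, (bounds$WL[2] - surf[, "WL"]) / diff(bounds$WL))),
    dE = pmin(1, pmax(0, (bounds$dE[2] - surf[, "dE"]) / diff(bounds$dE)))
  )
  D <- ifelse(apply(dmat == 0, 1, any), 0, exp(rowMeans(log(pmax(dmat, 1e-300)))))
  best <- g[which.max(D), ]

  cell <- c(20, 60, 20) / 100            # one oracle grid cell per factor
  expect_lte(abs(res1$optimum_actual[["temperature"]] - best$T), cell[1])
  expect_lte(abs(res1$optimum_actual[["time"]] - best$t), cell[2])
  expect_lte(abs(res1$optimum_actual[["glycerol"]] - best$C), cell[3])
  expect_gte(res1$D_composite, max(D) - 1e-6)
})

test_that("infeasible criteria fail loudly naming the binding response", {
  models <- od_reference_models(ref_space)["WL"]
  # WL never drops below -1 anywhere on the cube, so d is identically zero
  crit <- list(criterion("WL", "minimize", bound_low = -10, bound_high = -5))
  expect_error(optimize_desirability(models, crit, grid_n = 11),
               "infeasible.*WL")
})

test_that("validation error is the signed percent deviation with 20% acceptance", {
  expect_equal(as.numeric(validation_error(2.08, 1.26)), 39.4, tolerance = 0.05)
  expect_false(attr(validation_error(2.08, 1.26), "accepted"))
  aw_err <- validation_error(0.9105, 0.9117)
  expect_lt(abs(as.numeric(aw_err) + 0.13), 0.005)
  expect_true(attr(aw_err, "accepted"))
  expect_equal(as.numeric(validation_error(5, 5)), 0)
  expect_error(validation_error(0, 1), "nonzero")
})
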