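test_that("parameter construction enforces the growth regime", {
  p <- logistic_params(0.3, 1.2, 0.02875)
  expect_s3_class(p, "logistic_params")
  expect_error(logistic_params(-0.1, 1.2, 0.03), "x0")
  expect_error(logistic_params(0.3, 1.2, 0), "'a'")
  expect_error(logistic_params(0.3, 1.2, -0.02), "'a'")
  expect_error(logistic_params(1.2, 1.2, 0.03), "x0 < c")
  expect_error(logistic_params(1.5, 1.2, 0.03), "x0 < c")
  expect_error(logistic_params(NA, 1.2, 0.03), "finite")
})

test_that("the curve passes through x0 at birth and c/2 at inflection", {
  for (p in c(list(params_aggregate(), params_dialysis()),
              random_params(5, seed = 11))) {
    expect_equal(imt_at_age(p, 0), p$x0)
  }
  # published aggregate curve: inflection at (~38 y, 0.6 mm)
  agg <- params_aggregate()
  t_star <- inflection(agg)$t_star
  expect_equal(imt_at_age(agg, t_star), 0.6, tolerance = 1e-12)
  expect_error(imt_at_age(agg, Inf), "finite")
  expect_error(imt_at_age(agg, NA_real_), "finite")
})

test_that("closed form agrees with high-accuracy ODE integration", {
  skip_if_not_installed("deSolve")
  cases <- list(list(p = params_dialysis(), t = 58),   # legacy curve, ~0.866 mm
                list(p = params_aggregate(), t = 38.2),
                list(p = params_non_medicated(), t = 70))
  for (cs in cases) {
    p <- cs$p
    out <- deSolve::ode(y = c(x = p$x0), times = c(0, cs$t), parms = NULL,
                        func = function(t, y, parms) {
                          list(p$a * y * (1 - y / p$c))
                        },
                        rtol = 1e-12, atol = 1e-12)
    expect_equal(imt_at_age(p, cs$t), unname(out[2, "x"]), tolerance = 1e-8)
  }
  expect_equal(imt_at_age(params_dialysis(), 58), 0.866, tolerance = 1e-3)
})

test_that("growth_rate equals the derivative of the curve", {
  # published values at the inflection
  expect_equal(growth_rate(params_aggregate(), inflection(params_aggregate())$t_star),
               0.008625, tolerance = 1e-12)
  # finite-difference check at an arbitrary age on the legacy curve
  p <- params_dialysis()
  h <- 1e-5
  fd <- (imt_at_age(p, 62.5 + h) - imt_at_age(p, 62.5 - h)) / (2 * h)
  expect_equal(growth_rate(p, 62.5), fd, tolerance = 1e-8)
  # property: ODE consistency for random params and ages
  ts <- with_rng(21, runif(20, 0, 100))
  for (p in random_params(8, seed = 22)) {
    for (t in ts[1:5]) {
      fd <- (imt_at_age(p, t + h) - imt_at_age(p, t - h)) / (2 * h)
      expect_equal(growth_rate(p, t), fd, tolerance = 1e-6)
    }
  }
})

test_that("inflection summary matches the analytic identities", {
  # the three published cohort curves round to ages 38 / 21 / 40
  agg <- inflection(params_aggregate())
  expect_equal(agg$t_star, 38.21, tolerance = 1e-3)
  expect_equal(agg$x_star, 0.6)
  expect_equal(agg$max_slope, 0.008625)
  nm <- inflection(params_non_medicated())
  expect_equal(nm$t_star, 20.72, tolerance = 1e-3)
  expect_equal(nm$x_star, 0.45)
  expect_equal(nm$max_slope, 0.008915, tolerance = 1e-4)
  # growth rate at t_star equals the analytic maximum
  for (p in random_params(6, seed = 33)) {
    infl <- inflection(p)
    expect_equal(growth_rate(p, infl$t_star), infl$max_slope,
                 tolerance = 1e-12)
    expect_false(infl$pre_observation && p$x0 < p$c / 2)
  }
  # x0 = c/2 puts the inflection exactly at birth
  half <- logistic_params(0.6, 1.2, 0.05)
  expect_equal(inflection(half)$t_star, 0)
  expect_true(inflection(half)$pre_observation)
})

test_that("numeric maximization of the slope locates the inflection", {
  for (p in random_params(6, seed = 44)) {
    opt <- optimize(function(t) growth_rate(p, t), c(-50, 200),
                    maximum = TRUE, tol = 1e-9)
    infl <- inflection(p)
    expect_equal(opt$maximum, infl$t_star, tolerance = 1e-4)
    expect_equal(opt$objective, p$a * p$c / 4, tolerance = 1e-10)
  }
})

test_that("curve is bounded, monotone, symmetric and stable at extreme ages", {
  for (p in random_params(6, seed = 55)) {
    ts <- seq(-200, 300, by = 2.5)
    x <- imt_at_age(p, ts)
    expect_true(all(x > 0 & x < p$c))
    expect_true(all(diff(x) > 0))
    # sigmoid symmetry about the inflection
    infl <- inflection(p)
    d <- c(0.5, 3, 17, 60)
    expect_equal(imt_at_age(p, infl$t_star + d) + imt_at_age(p, infl$t_star - d),
                 rep(p$c, length(d)), tolerance = 1e-10)
    # limits, without overflow even when a*t is enormous
    expect_equal(imt_at_age(p, 1e6), p$c, tolerance = 1e-8)
    expect_equal(imt_at_age(p, -1e6), 0, tolerance = 1e-8)
    expect_true(is.finite(growth_rate(p, 1e6)))
    expect_equal(growth_rate(p, 1e6), 0, tolerance = 1e-8)
  }
})

test_that("mean_slope is the secant and reproduces the legacy comparison", {
  legacy <- params_dialysis()
  # slope of the legacy curve between ages 58 and 67: ~0.0266 mm/year
  expect_equal(mean_slope(legacy, 58, 67), 0.0265, tolerance = 0.02)
  expect_equal(mean_slope(legacy, 58, 67),
               (curve_value(legacy, 67) - curve_value(legacy, 58)) / 9,
               tolerance = 1e-12)
  # secant tends to the tangent as the interval shrinks
  p <- params_aggregate()
  expect_equal(mean_slope(p, 40, 40 + 1e-7), growth_rate(p, 40),
               tolerance = 1e-6)
  # over a lifespan-scale window the secant approaches (c - x0) / width
  expect_equal(mean_slope(p, 0, 200),
               (curve_value(p, 200) - p$x0) / 200, tolerance = 1e-12)
  expect_equal(mean_slope(p, 0, 200), 0.0045, tolerance = 0.01)
  expect_error(mean_slope(p, 67, 58), "greater")
  expect_error(mean_slope(p, 58, 58), "greater")
})

test_that("slope_profile is unimodal with its peak nearest the inflection", {
  nm <- params_non_medicated()
  prof <- slope_profile(nm, 0:100)
  expect_equal(prof$age[which.max(prof$slope)], 21)
  d <- diff(prof$slope)
  peak <- which.max(prof$slope)
  expect_true(all(d[seq_len(peak - 1)] > 0))
  expect_true(all(d[peak:length(d)] < 0))
  # single-point grid at the inflection returns the max slope
  agg <- params_aggregate()
  t_star <- inflection(agg)$t_star
  one <- slope_profile(agg, t_star)
  expect_equal(nrow(one), 1L)
  expect_equal(one$slope, 0.008625, tolerance = 1e-12)
  # slope symmetry about the inflection
  sym <- slope_profile(agg, t_star + c(-10, 10))
  expect_equal(sym$slope[1], sym$slope[2], tolerance = 1e-12)
  expect_error(slope_profile(agg, numeric(0)), "finite")
  expect_error(slope_profile(agg, c(10, 5, 20)), "increasing")
})
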