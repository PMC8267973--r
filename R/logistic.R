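#' Parameters of the logistic IMT growth curve
#'
#' Bundles the three parameters of the logistic growth model of carotid
#' intima-media thickness (IMT),
#' \deqn{x(t) = \frac{c\, x_0\, e^{at}}{c + x_0 (e^{at} - 1)},}
#' the solution of the logistic differential equation
#' \eqn{dx/dt = a x (1 - x/c)} with \eqn{x(0) = x_0}. Age \eqn{t} is
#' chronological age in years, with \eqn{t = 0} at birth; \eqn{x_0} is
#' therefore a model abstraction of IMT at birth, not a measured neonatal
#' value.
#'
#' @param x0 IMT at age 0, mm. Must be positive and strictly below `c`.
#' @param c Carrying capacity: the terminal IMT (mm) the curve converges to.
#' @param a Growth-rate coefficient, 1/year. Must be positive.
#'
#' @return An object of class `logistic_params`: a list with elements
#'   `x0`, `c`, `a`.
#'
#' @examples
#' p <- logistic_params(x0 = 0.3, c = 1.2, a = 0.02875)
#' imt_at_age(p, 38.2)
#' inflection(p)
#' @export
logistic_params <- function(x0, c, a) {
  for (nm in c("x0", "c", "a")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stopf("'%s' must be a single finite number", nm)
    }
  }
  if (x0 <= 0) stopf("'x0' must be > 0 (got %g)", x0)
  if (c <= 0) stopf("'c' must be > 0 (got %g)", c)
  if (a <= 0) stopf("'a' must be > 0 (got %g)", a)
  if (x0 >= c) {
    stopf("growth regime requires x0 < c (got x0 = %g, c = %g)", x0, c)
  }
  structure(list(x0 = x0, c = c, a = a), class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("Logistic IMT growth curve: x0 = %g mm, c = %g mm, a = %g /year\n",
              x$x0, x$c, x$a))
  invisible(x)
}

as_logistic_params <- function(x) {
  if (inherits(x, "logistic_params")) return(x)
  if (inherits(x, "imt_fit")) return(x$params)
  stopf("expected a 'logistic_params' or 'imt_fit' object")
}

# Unvalidated, vectorised curve evaluation; the two algebraically equivalent
# forms keep exp() bounded for arbitrarily large |a * t|.
logistic_eval <- function(x0, c, a, t) {
  at <- a * t
  ifelse(at > 0,
         c / (1 + ((c - x0) / x0) * exp(-at)),
         c * x0 * exp(at) / (c + x0 * (exp(at) - 1)))
}

check_age <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t))) {
    stopf("age 't' must be finite numeric")
  }
  invisible(t)
}

#' Evaluate the logistic IMT curve at given ages
#'
#' @param params A [logistic_params()] object.
#' @param t Ages in years (any finite real; the curve is defined for all
#'   ages). May be a vector.
#' @return IMT in mm, strictly within `(0, c)`.
#' @export
imt_at_age <- function(params, t) {
  params <- as_logistic_params(params)
  check_age(t)
  logistic_eval(params$x0, params$c, params$a, t)
}

#' Instantaneous IMT growth rate
#'
#' The right-hand side of the logistic differential equation evaluated on
#' the curve: \eqn{a\, x(t)\, (1 - x(t)/c)}, in mm/year. Equals the analytic
#' derivative of [imt_at_age()].
#'
#' @inheritParams imt_at_age
#' @return Slope in mm/year (always positive for valid parameters).
#' @export
growth_rate <- function(params, t) {
  params <- as_logistic_params(params)
  check_age(t)
  x <- logistic_eval(params$x0, params$c, params$a, t)
  params$a * x * (1 - x / params$c)
}

#' Inflection point of the logistic curve
#'
#' The age of fastest IMT growth. Analytically
#' \eqn{t^* = \ln((c - x_0)/x_0)/a}, where the curve passes through
#' \eqn{c/2} with slope \eqn{a c / 4}.
#'
#' @param params A [logistic_params()] object.
#' @return An object of class `inflection_summary` with elements
#'   `t_star` (years), `x_star` (mm, always `c/2`), `max_slope` (mm/year,
#'   always `a*c/4`), and `pre_observation` (`TRUE` when `x0 >= c/2`, i.e.
#'   the inflection falls at or before birth).
#' @examples
#' inflection(logistic_params(0.3, 1.2, 0.02875))  # t* ~ 38.2 years
#' @export
inflection <- function(params) {
  params <- as_logistic_params(params)
  t_star <- log((params$c - params$x0) / params$x0) / params$a
  structure(
    list(t_star = t_star,
         x_star = params$c / 2,
         max_slope = params$a * params$c / 4,
         pre_observation = t_star <= 0),
    class = "inflection_summary"
  )
}

#' @export
print.inflection_summary <- function(x, ...) {
  cat(sprintf("Inflection at age %.1f y (~%d): IMT %.4g mm, max slope %.4g mm/year\n",
              x$t_star, round_half_out(x$t_star), x$x_star, x$max_slope))
  if (x$pre_observation) {
    cat("note: inflection at or before birth (x0 >= c/2)\n")
  }
  invisible(x)
}

#' Average (secant) slope of the curve over an age interval
#'
#' `(x(t2) - x(t1)) / (t2 - t1)`, the mean IMT growth rate between two ages.
#'
#' @inheritParams imt_at_age
#' @param t1,t2 Interval endpoints in years, `t2 > t1`.
#' @return Mean slope in mm/year.
#' @export
mean_slope <- function(params, t1, t2) {
  params <- as_logistic_params(params)
  check_age(c(t1, t2))
  if (t2 <= t1) stopf("'t2' must be greater than 't1' (got %g <= %g)", t2, t1)
  (imt_at_age(params, t2) - imt_at_age(params, t1)) / (t2 - t1)
}

#' Growth-rate profile over an age grid
#'
#' Evaluates [growth_rate()] elementwise on an ordered age grid; the profile
#' is unimodal with its peak at the grid point nearest the inflection age.
#'
#' @inheritParams imt_at_age
#' @param age_grid Nonempty, strictly increasing ages in years.
#' @return A data frame with columns `age` and `slope` (mm/year).
#' @export
slope_profile <- function(params, age_grid) {
  params <- as_logistic_params(params)
  check_age(age_grid)
  if (length(age_grid) > 1L && any(diff(age_grid) <= 0)) {
    stopf("'age_grid' must be strictly increasing")
  }
  data.frame(age = age_grid, slope = growth_rate(params, age_grid))
}
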