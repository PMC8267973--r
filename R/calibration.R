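#' Sum of squared errors of a logistic curve against a cohort
#'
#' @param params A [logistic_params()] object.
#' @param data A cohort data frame with columns `age_years` and `imt_mm`
#'   (as produced by [generate_cohort()] or [read_imt_dataset()]).
#' @return SSE in mm^2; zero iff every observation lies on the curve.
#' @export
sse <- function(params, data) {
  params <- as_logistic_params(params)
  d <- check_dataset(data)
  sum((d$imt_mm - imt_at_age(params, d$age_years))^2)
}

check_dataset <- function(data) {
  if (!is.data.frame(data)) stopf("'data' must be a data frame")
  miss <- setdiff(c("age_years", "imt_mm"), names(data))
  if (length(miss)) stopf("'data' lacks required column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stopf("empty dataset")
  data
}

#' RMSE from an SSE under either denominator convention
#'
#' Published IMT model tables are not consistent about the root mean square
#' error denominator: some divide the SSE by `n - 1`, others by `n`. Both
#' dialects are supported explicitly.
#'
#' @param sse Sum of squared errors, mm^2.
#' @param n Number of observations.
#' @param dialect `"n_minus_1"` (default) or `"n"`.
#' @return RMSE in mm.
#' @examples
#' rmse_from_sse(1.689, 62)                  # 0.1664
#' rmse_from_sse(0.389, 11, dialect = "n")   # 0.1881
#' @export
rmse_from_sse <- function(sse, n, dialect = c("n_minus_1", "n")) {
  dialect <- match.arg(dialect)
  if (!is_count(n) || n < 2) stopf("'n' must be an integer >= 2")
  sqrt(sse / if (dialect == "n_minus_1") n - 1 else n)
}

new_imt_fit <- function(params, sse, n, rmse_dialect, r2,
                        converged = NA, n_starts = 0L,
                        age_range = c(NA_real_, NA_real_),
                        group = NA_character_) {
  structure(
    list(params = params,
         sse = sse,
         rmse = rmse_from_sse(sse, n, rmse_dialect),
         r2 = r2,
         n = as.integer(n),
         rmse_dialect = rmse_dialect,
         converged = converged,
         n_starts = as.integer(n_starts),
         age_range = as.numeric(age_range),
         group = group),
    class = "imt_fit"
  )
}

#' @export
print.imt_fit <- function(x, ...) {
  infl <- inflection(x$params)
  cat("Logistic IMT growth fit",
      if (!is.na(x$group)) sprintf("(group: %s)", x$group) else "", "\n")
  cat(sprintf("  x0 = %g mm, c = %g mm, a = %g /year  (n = %d)\n",
              x$params$x0, x$params$c, x$params$a, x$n))
  cat(sprintf("  SSE = %.4g mm^2, RMSE = %.4g mm (%s), R^2 = %.4g\n",
              x$sse, x$rmse, x$rmse_dialect, x$r2))
  cat(sprintf("  inflection [~%d y, %.4g mm], max slope %.4g mm/year\n",
              round_half_out(infl$t_star), infl$x_star, infl$max_slope))
  invisible(x)
}

r_squared <- function(resid_ss, imt) {
  sst <- sum((imt - mean(imt))^2)
  if (sst == 0) {
    if (resid_ss == 0) return(1)
    warning("zero variance in IMT with nonzero SSE; R^2 reported as -Inf",
            call. = FALSE)
    return(-Inf)
  }
  1 - resid_ss / sst
}

#' Goodness of fit of fixed parameters against a cohort
#'
#' Computes SSE, RMSE (under the chosen denominator dialect) and
#' \eqn{R^2 = 1 - SSE / \sum_i (y_i - \bar y)^2} for a given curve, without
#' re-fitting. \eqn{R^2} may be negative for a nonlinear model and is
#' reported as-is.
#'
#' @inheritParams sse
#' @param dialect RMSE denominator convention; see [rmse_from_sse()].
#' @param group Optional group label carried into the result.
#' @return An `imt_fit` object (with `converged = NA`; no optimization done).
#' @export
goodness_of_fit <- function(params, data, dialect = c("n_minus_1", "n"),
                            group = NA_character_) {
  params <- as_logistic_params(params)
  dialect <- match.arg(dialect)
  d <- check_dataset(data)
  if (nrow(d) < 2L) stopf("need at least 2 observations")
  s <- sse(params, d)
  new_imt_fit(params, s, nrow(d), dialect, r_squared(s, d$imt_mm),
              age_range = range(d$age_years), group = group)
}

#' Configuration for logistic curve fitting
#'
#' @param x0_bounds,c_bounds,a_bounds Lower/upper box bounds for each
#'   parameter. Defaults span all published IMT fits with wide margins:
#'   `x0` in `[0.01, 0.9]` mm, `c` in `[0.3, 3.0]` mm, `a` in
#'   `[0.001, 0.5]` /year.
#' @param n_starts Number of multi-start initial points (default 20).
#' @param seed Integer seed making the multi-start draw reproducible.
#' @param tol Optimizer relative tolerance.
#' @param rmse_dialect RMSE denominator convention; see [rmse_from_sse()].
#' @param method `"multistart"` (default): bounded Levenberg-Marquardt least
#'   squares from `n_starts` seeded starting points. `"grid"`: coarse grid
#'   over `(x0, c)` with one-dimensional optimization of `a` in each cell,
#'   reproducing the "round parameter" fitting style.
#' @param grid_step Named step sizes for the grid method, mm.
#' @return A `fit_config` list.
#' @export
fit_config <- function(x0_bounds = c(0.01, 0.9),
                       c_bounds = c(0.3, 3.0),
                       a_bounds = c(0.001, 0.5),
                       n_starts = 20L,
                       seed = 1L,
                       tol = 1e-10,
                       rmse_dialect = c("n_minus_1", "n"),
                       method = c("multistart", "grid"),
                       grid_step = c(x0 = 0.025, c = 0.05)) {
  rmse_dialect <- match.arg(rmse_dialect)
  method <- match.arg(method)
  for (b in list(x0_bounds, c_bounds, a_bounds)) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1] >= b[2]) {
      stopf("each bounds argument must be a finite (lower, upper) pair")
    }
  }
  if (x0_bounds[1] <= 0 || a_bounds[1] <= 0 || c_bounds[1] <= 0) {
    stopf("all lower bounds must be positive")
  }
  if (x0_bounds[2] >= c_bounds[2]) {
    stopf("upper bound on x0 must lie below the upper bound on c")
  }
  if (!is_count(n_starts) || n_starts < 1) stopf("'n_starts' must be >= 1")
  structure(list(x0_bounds = x0_bounds, c_bounds = c_bounds,
                 a_bounds = a_bounds, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), tol = tol,
                 rmse_dialect = rmse_dialect, method = method,
                 grid_step = grid_step),
            class = "fit_config")
}

# One bounded Levenberg-Marquardt descent from a given start; returns NULL
# on failure or when the solution leaves the growth regime (x0 >= c).
one_nls_fit <- function(d, start, config) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      imt_mm ~ logistic_eval(x0, cc, a, age_years),
      data = d,
      start = list(x0 = start[1], cc = start[2], a = start[3]),
      lower = c(config$x0_bounds[1], config$c_bounds[1], config$a_bounds[1]),
      upper = c(config$x0_bounds[2], config$c_bounds[2], config$a_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = config$tol,
                                           ptol = config$tol)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (cf[["x0"]] >= cf[["cc"]]) return(NULL)
  list(x0 = cf[["x0"]], c = cf[["cc"]], a = cf[["a"]],
       sse = sum(stats::resid(fit)^2))
}

fit_multistart <- function(d, config) {
  lo <- c(config$x0_bounds[1], config$c_bounds[1], config$a_bounds[1])
  hi <- c(config$x0_bounds[2], config$c_bounds[2], config$a_bounds[2])
  clip <- function(v) pmin(pmax(v, lo), hi)
  # one data-informed start, the rest seeded uniform draws over the box
  informed <- clip(c(min(d$imt_mm) * 0.9,
                     max(d$imt_mm) * 1.25,
                     0.03))
  if (informed[1] >= informed[2]) informed[1] <- informed[2] / 2
  starts <- list(informed)
  if (config$n_starts > 1L) {
    rand <- with_seed(config$seed, {
      m <- matrix(stats::runif(3 * (config$n_starts - 1L)),
                  ncol = 3, byrow = TRUE)
      sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
    })
    rand[, 1] <- pmin(rand[, 1], rand[, 2] * 0.9)  # keep x0 < c at start
    starts <- c(starts, lapply(seq_len(nrow(rand)), function(i) rand[i, ]))
  }
  sols <- Filter(Negate(is.null),
                 lapply(starts, function(s) one_nls_fit(d, s, config)))
  if (length(sols) == 0L) {
    stopf(paste0("logistic fit failed to converge from all %d starts ",
                 "(n = %d observations, age range %g-%g)"),
          config$n_starts, nrow(d), min(d$age_years), max(d$age_years))
  }
  tab <- do.call(rbind, lapply(sols, as.data.frame))
  best <- tab[order(tab$sse, tab$x0, tab$c, tab$a), ][1, ]
  list(best = best, n_tried = config$n_starts)
}

fit_grid <- function(d, config) {
  # anchor the grid on multiples of the step so "round" values are on it
  grid_seq <- function(lo, hi, step) {
    seq(step * ceiling(lo / step), hi, by = step)
  }
  x0s <- grid_seq(config$x0_bounds[1], config$x0_bounds[2],
                  config$grid_step[["x0"]])
  cs <- grid_seq(config$c_bounds[1], config$c_bounds[2],
                 config$grid_step[["c"]])
  cells <- expand.grid(x0 = x0s, c = cs)
  cells <- cells[cells$x0 < cells$c, ]
  sse_a <- function(x0, cc) {
    opt <- stats::optimize(
      function(a) sum((d$imt_mm - logistic_eval(x0, cc, a, d$age_years))^2),
      interval = config$a_bounds, tol = 1e-12)
    c(a = opt$minimum, sse = opt$objective)
  }
  res <- t(mapply(sse_a, cells$x0, cells$c))
  tab <- data.frame(x0 = cells$x0, c = cells$c, a = res[, "a"],
                    sse = res[, "sse"])
  best <- tab[order(tab$sse, tab$x0, tab$c, tab$a), ][1, ]
  list(best = best, n_tried = nrow(cells))
}

#' Fit the logistic IMT growth curve to a cohort
#'
#' Identifies `(x0, c, a)` minimizing the sum of squared errors over a
#' bounded box, either by seeded multi-start bounded Levenberg-Marquardt
#' least squares (default) or by a coarse grid over `(x0, c)` with
#' one-dimensional optimization of `a`. Deterministic given the config seed;
#' the best solution is selected by lowest SSE with ties broken by the
#' lexicographically smallest `(x0, c, a)`.
#'
#' @param data Cohort data frame with `age_years` and `imt_mm` columns and
#'   at least 4 rows (three free parameters).
#' @param config A [fit_config()] object.
#' @param group Optional group label carried into the result.
#' @return An `imt_fit` object: calibrated `params` plus `sse`, `rmse`,
#'   `r2`, `n`, convergence diagnostics and the observed age range.
#' @examples
#' coh <- generate_cohort(cohort_spec("aggregate", 31, c(19, 74),
#'                        logistic_params(0.3, 1.2, 0.02875),
#'                        noise_sd = 0, seed = 1))
#' fit_logistic(coh)  # recovers the generating parameters
#' @export
fit_logistic <- function(data, config = fit_config(), group = NA_character_) {
  d <- check_dataset(data)
  if (!inherits(config, "fit_config")) stopf("'config' must be a fit_config")
  if (nrow(d) < 4L) stopf("need at least 4 observations to fit 3 parameters")
  if (length(unique(d$age_years)) == 1L) {
    stopf("ages are all identical; the growth curve is not identifiable")
  }
  if (length(unique(d$imt_mm)) == 1L) {
    warning("all IMT values identical; boundary solution permitted",
            call. = FALSE)
  }
  # canonical row order makes the fit invariant to observation order
  d <- d[order(d$age_years, d$imt_mm), , drop = FALSE]
  res <- switch(config$method,
                multistart = fit_multistart(d, config),
                grid = fit_grid(d, config))
  best <- res$best
  params <- logistic_params(best$x0, best$c, best$a)
  fit <- new_imt_fit(params, best$sse, nrow(d), config$rmse_dialect,
                     r_squared(best$sse, d$imt_mm),
                     converged = TRUE, n_starts = res$n_tried,
                     age_range = range(d$age_years), group = group)
  fit
}
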