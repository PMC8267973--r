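# Shared fixtures: the published per-group curve parameters and small
# reusable oracles. Fixtures are built in code; nothing is read from disk.

params_aggregate <- function() logistic_params(x0 = 0.3, c = 1.2, a = 0.02875)
params_non_medicated <- function() logistic_params(x0 = 0.275, c = 0.9, a = 0.03962)
params_medicated <- function() logistic_params(x0 = 0.325, c = 1.25, a = 0.02625)
params_dialysis <- function() logistic_params(x0 = 0.05, c = 1.8, a = 0.06)

# Random valid parameter triples for property-style tests; growth rates are
# kept in the physiological 0.01-0.08 /year range so the curve does not
# saturate to double-precision equality with c on the test age grids.
random_params <- function(n, seed) {
  with_rng(seed, replicate(n, {
    x0 <- runif(1, 0.02, 0.6)
    cc <- runif(1, x0 * 1.5, 3)
    a <- runif(1, 0.01, 0.08)
    logistic_params(x0, cc, a)
  }, simplify = FALSE))
}

with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

curve_value <- function(p, t) p$c / (1 + ((p$c - p$x0) / p$x0) * exp(-p$a * t))

# Brute-force SSE minimization over a dense (x0, c, a) grid: the independent
# oracle for fit_logistic on small cohorts.
grid_oracle_sse <- function(data, x0_bounds = c(0.01, 0.9),
                            c_bounds = c(0.3, 3.0), a_bounds = c(0.001, 0.5),
                            n_grid = 50) {
  g <- expand.grid(x0 = seq(x0_bounds[1], x0_bounds[2], length.out = n_grid),
                   c = seq(c_bounds[1], c_bounds[2], length.out = n_grid),
                   a = seq(a_bounds[1], a_bounds[2], length.out = n_grid))
  g <- g[g$x0 < g$c, ]
  total <- numeric(nrow(g))
  for (i in seq_len(nrow(data))) {
    x <- g$c / (1 + ((g$c - g$x0) / g$x0) * exp(-g$a * data$age_years[i]))
    total <- total + (data$imt_mm[i] - x)^2
  }
  min(total)
}

# Minimal cohort data frame from raw vectors.
make_data <- function(age, imt) {
  data.frame(patient_id = sprintf("P%03d", seq_along(age)),
             age_years = age, imt_mm = imt, stringsAsFactors = FALSE)
}
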