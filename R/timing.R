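#' Recommend a statin-treatment start age from a fitted curve
#'
#' Treatment that lowers the slope of the IMT growth curve removes the most
#' future thickening when applied where the curve is steepest, i.e. at the
#' inflection point. The recommended start age is therefore the inflection
#' age rounded to the nearest integer year. A caution flag is set when the
#' inflection falls outside the cohort's observed age range (an
#' extrapolated recommendation), and when the inflection lies at or before
#' birth (`x0 >= c/2`) the recommendation carries an "already past the
#' steepest point" advisory instead of a usable age.
#'
#' @param fit An `imt_fit` object (or bare [logistic_params()], in which
#'   case no observed age range is available and the extrapolation flag is
#'   `NA`).
#' @return A `timing_recommendation` with `start_age` (integer years),
#'   `inflection` (an `inflection_summary`), `extrapolated`, `advisory` and
#'   a `rationale` string.
#' @examples
#' recommend_start_age(logistic_params(0.3, 1.2, 0.02875))  # age 38
#' @export
recommend_start_age <- function(fit) {
  params <- as_logistic_params(fit)
  infl <- inflection(params)
  start_age <- as.integer(round_half_out(infl$t_star))
  age_range <- if (inherits(fit, "imt_fit")) fit$age_range else c(NA_real_, NA_real_)
  extrapolated <- if (any(is.na(age_range))) NA else
    infl$t_star < age_range[1] || infl$t_star > age_range[2]
  advisory <- if (infl$pre_observation) {
    "inflection at or before birth: the cohort is already past the steepest point of the curve"
  } else {
    NA_character_
  }
  rationale <- sprintf(
    paste0("IMT growth is fastest at the inflection point (age %.1f y, ",
           "slope %.4g mm/year); slope reduction by statins removes the ",
           "most future thickening when started there."),
    infl$t_star, infl$max_slope)
  structure(list(start_age = start_age, inflection = infl,
                 extrapolated = extrapolated, advisory = advisory,
                 rationale = rationale),
            class = "timing_recommendation")
}

#' @export
print.timing_recommendation <- function(x, ...) {
  if (!is.na(x$advisory)) {
    cat("Advisory:", x$advisory, "\n")
  } else {
    cat(sprintf("Recommended statin start age: %d years\n", x$start_age))
  }
  cat(x$rationale, "\n")
  if (isTRUE(x$extrapolated)) {
    cat("caution: inflection lies outside the observed age range (extrapolated)\n")
  }
  invisible(x)
}

#' Compare two fitted groups by inflection timing and peak slope
#'
#' @param fit_a,fit_b `imt_fit` objects (or bare [logistic_params()]).
#' @param labels Length-2 group labels for the profile table.
#' @param age_grid Shared age grid for the slope profiles (years).
#' @return A `group_comparison` with `delta_inflection_age` (rounded
#'   inflection age of A minus B, years), `max_slope_ratio` (A over B),
#'   `max_slope_difference` (mm/year) and a long `slope_profiles` table.
#' @examples
#' agg <- logistic_params(0.3, 1.2, 0.02875)
#' nm <- logistic_params(0.275, 0.9, 0.03962)
#' compare_groups(agg, nm)$delta_inflection_age  # 17 years later
#' @export
compare_groups <- function(fit_a, fit_b, labels = c("A", "B"),
                           age_grid = 0:100) {
  ia <- inflection(as_logistic_params(fit_a))
  ib <- inflection(as_logistic_params(fit_b))
  profiles <- slope_figure_table(stats::setNames(list(fit_a, fit_b), labels),
                                 age_grid)
  structure(
    list(delta_inflection_age =
           round_half_out(ia$t_star) - round_half_out(ib$t_star),
         max_slope_ratio = ia$max_slope / ib$max_slope,
         max_slope_difference = ia$max_slope - ib$max_slope,
         labels = labels,
         slope_profiles = profiles),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s vs %s):\n", x$labels[1], x$labels[2]))
  cat(sprintf("  inflection age difference: %+d years\n",
              as.integer(x$delta_inflection_age)))
  cat(sprintf("  max slope ratio: %.4g, difference: %+.4g mm/year\n",
              x$max_slope_ratio, x$max_slope_difference))
  invisible(x)
}

#' Long-format slope profiles for several fitted groups
#'
#' Evaluates each group's growth-rate curve on a common age grid, in long
#' format for export or plotting — the per-group slope-versus-age panel
#' from which the steepest fragment of each curve can be read off.
#'
#' @param fits Nonempty named list of `imt_fit` or [logistic_params()]
#'   objects; unnamed lists get `group1`, `group2`, ... labels.
#' @param age_grid Nonempty, strictly increasing ages in years.
#' @return A data frame with columns `group`, `age`, `slope` (mm/year), one
#'   row per (group, age).
#' @export
slope_figure_table <- function(fits, age_grid = 0:100) {
  if (!is.list(fits) || length(fits) == 0L) {
    stopf("'fits' must be a nonempty list")
  }
  nms <- names(fits)
  if (is.null(nms) || any(nms == "")) {
    nms <- paste0("group", seq_along(fits))
  }
  do.call(rbind, lapply(seq_along(fits), function(i) {
    prof <- slope_profile(as_logistic_params(fits[[i]]), age_grid)
    data.frame(group = nms[i], age = prof$age, slope = prof$slope,
               stringsAsFactors = FALSE)
  }))
}

#' Plot slope profiles by group
#'
#' Renders the output of [slope_figure_table()]: one growth-rate curve per
#' group over age, peaks marking the steepest fragment of each group's IMT
#' trajectory.
#'
#' @param profiles Data frame from [slope_figure_table()].
#' @return A ggplot object when ggplot2 is installed, otherwise a base
#'   graphics plot (invisibly).
#' @export
plot_slope_profiles <- function(profiles) {
  stopifnot(all(c("group", "age", "slope") %in% names(profiles)))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggplot(profiles,
                    ggplot2::aes(x = .data$age, y = .data$slope,
                                 colour = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "age (years)", y = "IMT growth rate (mm/year)",
                    colour = "group")
  } else {
    groups <- split(profiles, profiles$group)
    plot(NA, xlim = range(profiles$age), ylim = range(profiles$slope),
         xlab = "age (years)", ylab = "IMT growth rate (mm/year)")
    for (i in seq_along(groups)) {
      lines(groups[[i]]$age, groups[[i]]$slope, col = i, lty = i)
    }
    legend("topright", legend = names(groups), col = seq_along(groups),
           lty = seq_along(groups))
    invisible(NULL)
  }
}
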