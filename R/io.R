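# Column aliases accepted on input; first name is canonical.
.col_aliases <- list(
  patient_id = c("patient_id", "id", "patient", "subject_id"),
  sex = c("sex", "gender"),
  group = c("group", "cohort", "clinical_group"),
  statin_status = c("statin_status", "statin", "on_statin"),
  statin_drug = c("statin_drug", "drug", "statin_name"),
  statin_dose_mg = c("statin_dose_mg", "dose_mg", "dose"),
  statin_duration_months = c("statin_duration_months", "duration_months",
                             "treatment_months"),
  age_years = c("age_years", "age", "age_y"),
  side = c("side", "artery", "artery_side"),
  imt_mm = c("imt_mm", "imt", "imt_value")
)

#' Read an IMT cohort dataset from delimited text
#'
#' Reads a header-bearing delimited file (comma by default, tab
#' auto-detected), normalizes known column-name aliases to the standard
#' schema, applies the physiological screens (age in (0, 120] years, IMT in
#' (0, 5) mm) and then the requested filters. Unknown columns are preserved.
#' Row counts at each stage (read, screened, filtered) are reported so group
#' splits remain auditable.
#'
#' @param path Path to a CSV/TSV file.
#' @param group,sex,statin_status Optional filters; each keeps rows whose
#'   column equals any of the given values. Filters compose (AND).
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param quiet Suppress the per-stage row-count messages.
#' @return A data frame in the standard cohort schema; required columns are
#'   `patient_id`, `age_years`, `imt_mm`.
#' @export
read_imt_dataset <- function(path, group = NULL, sex = NULL,
                             statin_status = NULL, sep = NULL,
                             quiet = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    if (length(header) == 0L) stopf("empty file: %s", path)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  for (canon in names(.col_aliases)) {
    hit <- intersect(.col_aliases[[canon]], names(raw))
    if (length(hit) > 0L && !(canon %in% names(raw))) {
      names(raw)[names(raw) == hit[1]] <- canon
    }
  }
  required <- c("patient_id", "age_years", "imt_mm")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stopf("dataset %s lacks required column(s): %s (found: %s)",
          path, paste(miss, collapse = ", "),
          paste(names(raw), collapse = ", "))
  }
  if (nrow(raw) == 0L) stopf("empty dataset (header only): %s", path)
  for (opt in c("sex", "group", "side")) {
    if (!(opt %in% names(raw))) raw[[opt]] <- "unspecified"
  }
  if (!("statin_status" %in% names(raw))) raw$statin_status <- NA_character_
  n_read <- nrow(raw)
  ok <- is.finite(raw$age_years) & raw$age_years > 0 & raw$age_years <= 120 &
    is.finite(raw$imt_mm) & raw$imt_mm > 0 & raw$imt_mm < 5
  d <- raw[ok, , drop = FALSE]
  n_screened <- nrow(d)
  keep <- rep(TRUE, nrow(d))
  if (!is.null(group)) keep <- keep & d$group %in% group
  if (!is.null(sex)) keep <- keep & d$sex %in% sex
  if (!is.null(statin_status)) keep <- keep & d$statin_status %in% statin_status
  d <- d[keep, , drop = FALSE]
  if (!quiet) {
    message(sprintf("read %d rows; %d passed physiological screen; %d after filters",
                    n_read, n_screened, nrow(d)))
  }
  if (nrow(d) == 0L) stopf("no observations remain after screening/filtering")
  rownames(d) <- NULL
  d
}

#' Write an IMT cohort dataset as delimited text
#'
#' Numeric columns are written with full double precision so that
#' `read_imt_dataset(write_imt_dataset(d))` round-trips every value exactly.
#'
#' @param data Cohort data frame.
#' @param path Output path.
#' @param sep Field separator (comma default; use `"\t"` for TSV).
#' @return `path`, invisibly.
#' @export
write_imt_dataset <- function(data, path, sep = ",") {
  d <- check_dataset(data)
  out <- d
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' @param fit An `imt_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "imt_fit"))
  infl <- inflection(fit$params)
  obj <- list(
    params = fit$params[c("x0", "c", "a")],
    sse = fit$sse, rmse = fit$rmse, r2 = fit$r2, n = fit$n,
    rmse_dialect = fit$rmse_dialect, converged = fit$converged,
    n_starts = fit$n_starts, age_range = fit$age_range, group = fit$group,
    inflection = list(t_star = infl$t_star, x_star = infl$x_star,
                      max_slope = infl$max_slope)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fit result back from JSON
#'
#' @param path Path written by [write_fit_json()].
#' @return An `imt_fit` object.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_imt_fit(logistic_params(obj$params$x0, obj$params$c, obj$params$a),
              sse = obj$sse, n = obj$n, rmse_dialect = obj$rmse_dialect,
              r2 = obj$r2,
              converged = if (is.null(obj$converged)) NA else obj$converged,
              n_starts = if (is.null(obj$n_starts)) 0L else obj$n_starts,
              age_range = if (is.null(obj$age_range)) c(NA_real_, NA_real_)
                          else obj$age_range,
              group = if (is.null(obj$group)) NA_character_ else obj$group)
}

#' Fit and summarize every group in one cohort file
#'
#' Fits the logistic growth curve to the full dataset (the patient
#' aggregate) and, when statin status is recorded, to the non-medicated and
#' statin-medicated subsets, returning one summary row per group with the
#' calibrated parameters, goodness-of-fit statistics, rounded inflection
#' age, inflection IMT, and maximum slope.
#'
#' @param data Cohort data frame.
#' @param config A [fit_config()].
#' @return A data frame with columns `group`, `x0`, `c`, `a`, `sse`,
#'   `rmse`, `r2`, `infl_age`, `infl_imt`, `max_slope`, `n`.
#' @export
cohort_report <- function(data, config = fit_config()) {
  d <- check_dataset(data)
  subsets <- list(aggregate = d)
  if ("statin_status" %in% names(d) && !all(is.na(d$statin_status))) {
    nm <- d[d$statin_status %in% "none", , drop = FALSE]
    sm <- d[d$statin_status %in% "on", , drop = FALSE]
    if (nrow(nm) >= 4L) subsets$non_medicated <- nm
    if (nrow(sm) >= 4L) subsets$statin_medicated <- sm
  }
  rows <- lapply(names(subsets), function(g) {
    fit <- fit_logistic(subsets[[g]], config, group = g)
    infl <- inflection(fit$params)
    data.frame(group = g, x0 = fit$params$x0, c = fit$params$c,
               a = fit$params$a, sse = fit$sse, rmse = fit$rmse,
               r2 = fit$r2,
               infl_age = as.integer(round_half_out(infl$t_star)),
               infl_imt = infl$x_star, max_slope = infl$max_slope,
               n = fit$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
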