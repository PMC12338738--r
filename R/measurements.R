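# Long-format multiplex cytokine measurement tables: validation, I/O, LOQ
# censoring, and plate-level QC metrics.

MEASUREMENT_COLS <- c("specimen_id", "well_id", "treatment", "analyte",
                      "time_h", "concentration_pg_ml", "censor")
TREATMENT_LEVELS <- c("IgG", "ICI", "stim", "sequential")
CENSOR_LEVELS <- c("within", "below_lloq", "clamped_uloq")

#' Validate a long-format measurement table
#'
#' Checks the schema used throughout the package: one row per
#' specimen/well/treatment/analyte/time with a non-negative concentration in
#' pg/mL and a censoring flag in `within`, `below_lloq`, `clamped_uloq`.
#' Duplicate (well, analyte, time) rows, negative or non-numeric
#' concentrations and unknown flags are schema errors naming the offending
#' rows.
#'
#' @param tbl a data frame.
#' @return the validated table as a tibble (censor filled with `"within"`
#'   when the column is absent, i.e. a raw, un-censored export).
#' @export
validate_measurements <- function(tbl) {
  tbl <- as_tibble(tbl)
  if (!"censor" %in% names(tbl)) tbl$censor <- "within"
  miss <- setdiff(MEASUREMENT_COLS, names(tbl))
  if (length(miss)) {
    abort(paste0("measurement table missing columns: ", toString(miss)))
  }
  tbl <- tbl[MEASUREMENT_COLS]
  if (!is.numeric(tbl$time_h) || !is.numeric(tbl$concentration_pg_ml)) {
    abort("`time_h` and `concentration_pg_ml` must be numeric")
  }
  bad <- which(!is.finite(tbl$concentration_pg_ml) | tbl$concentration_pg_ml < 0)
  if (length(bad)) {
    abort(paste0("non-finite or negative concentration in row(s): ",
                 toString(utils::head(bad, 5))))
  }
  bad <- which(!tbl$censor %in% CENSOR_LEVELS)
  if (length(bad)) {
    abort(paste0("unknown censor flag in row(s): ", toString(utils::head(bad, 5))))
  }
  bad <- which(!tbl$treatment %in% TREATMENT_LEVELS)
  if (length(bad)) {
    abort(paste0("unknown treatment in row(s): ", toString(utils::head(bad, 5)),
                 " (expected one of ", toString(TREATMENT_LEVELS), ")"))
  }
  key <- paste(tbl$well_id, tbl$analyte, tbl$time_h, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(paste0("duplicate (well_id, analyte, time_h) in row(s): ",
                 toString(utils::head(dup, 5))))
  }
  tbl
}

#' Read and write measurement tables
#'
#' Delimited text (comma-separated, UTF-8) with header
#' `specimen_id,well_id,treatment,analyte,time_h,concentration_pg_ml,censor`;
#' the `censor` column may be omitted in raw exports. Write-then-read is the
#' identity on values and flags.
#'
#' @param path file path.
#' @return [read_measurements()] returns a validated tibble;
#'   [write_measurements()] returns `path` invisibly.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) abort(paste0("measurement file not found: ", path))
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character(),
    time_h = readr::col_double(),
    concentration_pg_ml = readr::col_double()
  ), progress = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(paste0("malformed measurement file, e.g. row ", probs$row[1],
                 ": expected ", probs$expected[1], ", got ", probs$actual[1]))
  }
  validate_measurements(raw)
}

#' @rdname read_measurements
#' @param tbl a validated measurement table.
#' @export
write_measurements <- function(tbl, path) {
  readr::write_csv(validate_measurements(tbl), path)
  invisible(path)
}

#' Apply limit-of-quantitation censoring
#'
#' Concentrations above an analyte's ULOQ are set to the ULOQ and flagged
#' `clamped_uloq`; concentrations below the LLOQ are retained unchanged but
#' flagged `below_lloq` (downstream analyses decide whether to drop them);
#' analytes excluded by the panel are removed entirely. The operation is
#' idempotent: a value sitting exactly at the ULOQ keeps its `clamped_uloq`
#' flag on re-application.
#'
#' @param tbl a measurement table (see [validate_measurements()]).
#' @param panel an [analyte_panel()] covering every analyte in `tbl`.
#' @return the censored table.
#' @export
apply_loq <- function(tbl, panel) {
  tbl <- validate_measurements(tbl)
  stopifnot(inherits(panel, "analyte_panel"))
  unknown <- setdiff(unique(tbl$analyte), panel$analyte)
  if (length(unknown)) {
    abort(paste0("analytes absent from panel: ", toString(unknown)))
  }
  tbl <- tbl[tbl$analyte %in% panel_analytes(panel), , drop = FALSE]
  idx <- match(tbl$analyte, panel$analyte)
  lloq <- panel$lloq[idx]
  uloq <- panel$uloq[idx]
  conc <- tbl$concentration_pg_ml
  censor <- dplyr::case_when(
    conc > uloq ~ "clamped_uloq",
    conc < lloq ~ "below_lloq",
    tbl$censor == "clamped_uloq" & conc == uloq ~ "clamped_uloq",
    TRUE ~ "within"
  )
  tbl$concentration_pg_ml <- pmin(conc, uloq)
  tbl$censor <- censor
  tbl
}

#' Percent of panel analytes quantifiable per well
#'
#' For each well, 100 x (number of analytes with at least one record not
#' flagged `below_lloq`) / (number of analytes in the panel after
#' exclusions). LOQ censoring must already have been applied.
#'
#' @inheritParams apply_loq
#' @return tibble with `well_id`, `specimen_id`, `n_above`, `pct_above_lloq`.
#' @export
pct_above_lloq <- function(tbl, panel) {
  tbl <- validate_measurements(tbl)
  stopifnot(inherits(panel, "analyte_panel"))
  denom <- length(panel_analytes(panel))
  if (denom == 0L) abort("panel has no analytes after exclusions")
  tbl |>
    group_by(.data$specimen_id, .data$well_id, .data$analyte) |>
    summarise(above = any(.data$censor != "below_lloq"), .groups = "drop") |>
    group_by(.data$specimen_id, .data$well_id) |>
    summarise(n_above = sum(.data$above), .groups = "drop") |>
    mutate(pct_above_lloq = 100 * .data$n_above / denom)
}

#' Replicate-well coefficient of variation
#'
#' CV% (sample, n-1 standard deviation over mean, on raw concentrations) of
#' replicate wells within each (specimen, analyte, treatment, time) group,
#' after dropping rows flagged `below_lloq`. Groups with fewer than two
#' usable wells, or mean zero, are flagged missing (`cv_pct = NA`) rather
#' than erroring.
#'
#' @param tbl a censored measurement table.
#' @return tibble with the group keys, `n_wells`, and `cv_pct`.
#' @seealso [median_cv_by_specimen()] for the per-specimen summary.
#' @export
replicate_cv <- function(tbl) {
  tbl <- validate_measurements(tbl)
  tbl |>
    filter(.data$censor != "below_lloq") |>
    group_by(.data$specimen_id, .data$analyte, .data$treatment, .data$time_h) |>
    summarise(
      n_wells = dplyr::n_distinct(.data$well_id),
      cv_pct = cv_percent(.data$concentration_pg_ml),
      .groups = "drop"
    )
}

#' Median replicate CV per specimen
#'
#' The specimen-level variability summary: the median over analyte-level
#' replicate CVs for each specimen.
#'
#' @param cv_tbl output of [replicate_cv()].
#' @return tibble with `specimen_id` and `median_cv_pct`.
#' @export
median_cv_by_specimen <- function(cv_tbl) {
  cv_tbl |>
    group_by(.data$specimen_id) |>
    summarise(median_cv_pct = stats::median(.data$cv_pct, na.rm = TRUE),
              .groups = "drop")
}

#' Metabolic-activity rate from a CCK8 absorbance course
#'
#' Least-squares slope of absorbance against time (abs/hour). With exactly
#' two points this equals the difference quotient.
#'
#' @param time_h numeric times in hours (>= 2 distinct values).
#' @param absorbance matching absorbance readings.
#' @return slope in absorbance units per hour.
#' @examples
#' cck8_rate(c(0, 24), c(0.10, 0.58))  # 0.02 abs/hour
#' @export
cck8_rate <- function(time_h, absorbance) {
  if (length(time_h) < 2L) abort("need at least two absorbance readings")
  if (anyDuplicated(time_h)) abort("duplicate time points in absorbance course")
  ls_slope(time_h, absorbance)
}

#' Viable-voxel fraction of a labeled volume
#'
#' @param viable,nonviable non-negative voxel counts; their sum must be
#'   positive.
#' @return viable / (viable + nonviable), in \[0, 1\].
#' @export
viable_fraction <- function(viable, nonviable) {
  check_scalar(viable, "viable", function(v) v >= 0, "non-negative")
  check_scalar(nonviable, "nonviable", function(v) v >= 0, "non-negative")
  total <- viable + nonviable
  if (total <= 0) abort("total voxel count must be positive")
  viable / total
}
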