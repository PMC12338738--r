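# Sequential same-well treatment scoring: per-phase least-squares slopes of
# cumulative cytokine concentration, the treatment/control slope fold
# change, its maximum across replicate wells, and the
# increase / no-change / decrease classification.

#' Define a sequential-treatment phase design
#'
#' Control and treatment windows share the switch time: conditioned media is
#' sampled at (approximately) the nominal times, the control (IgG) phase
#' runs from the first sample to the switch, and the treatment (ICI) phase
#' from the switch to the last sample. With three samples the switch-time
#' sample is the only way both windows contain two points, so it is included
#' in both.
#'
#' @param control_window numeric length-2, `[t_start, t_switch]` hours.
#' @param treatment_window numeric length-2, `[t_switch, t_end]` hours; must
#'   start where the control window ends.
#' @param nominal_times intended collection times (hours); actual sample
#'   timestamps are used when scoring, these are documentation/fallback.
#' @return object of class `phase_design`.
#' @export
phase_design <- function(control_window = c(4, 20),
                         treatment_window = c(20, 48),
                         nominal_times = c(4, 20, 48)) {
  if (length(control_window) != 2L || length(treatment_window) != 2L ||
      control_window[1] >= control_window[2] ||
      treatment_window[1] >= treatment_window[2]) {
    abort("windows must be increasing [start, end] pairs")
  }
  if (control_window[2] != treatment_window[1]) {
    abort("treatment window must start at the switch time (control window end)")
  }
  structure(
    list(control_window = as.numeric(control_window),
         treatment_window = as.numeric(treatment_window),
         nominal_times = as.numeric(nominal_times),
         t_start = control_window[1], t_switch = control_window[2],
         t_end = treatment_window[2]),
    class = "phase_design"
  )
}

#' Per-phase secretion-rate slopes of one time course
#'
#' Least-squares slope of cumulative concentration against actual sample
#' time within each phase window (both window bounds inclusive, so the
#' switch-time sample belongs to both). With exactly two samples per window
#' this is the difference quotient.
#'
#' @param time_h,concentration the time course (hours, pg/mL).
#' @param design a [phase_design()].
#' @return list with `control_slope` and `treatment_slope` (pg/mL/h).
#' @examples
#' phase_slopes(c(4, 20, 48), c(10, 26, 110), phase_design())
#' @export
phase_slopes <- function(time_h, concentration, design = phase_design()) {
  stopifnot(inherits(design, "phase_design"),
            length(time_h) == length(concentration))
  ord <- order(time_h)
  time_h <- time_h[ord]
  concentration <- concentration[ord]
  in_ctrl <- time_h >= design$control_window[1] &
    time_h <= design$control_window[2]
  in_trt <- time_h >= design$treatment_window[1] &
    time_h <= design$treatment_window[2]
  if (sum(in_ctrl) < 2L) {
    abort(sprintf("control window [%g, %g] h contains %d sample(s); need >= 2",
                  design$control_window[1], design$control_window[2],
                  sum(in_ctrl)))
  }
  if (sum(in_trt) < 2L) {
    abort(sprintf("treatment window [%g, %g] h contains %d sample(s); need >= 2",
                  design$treatment_window[1], design$treatment_window[2],
                  sum(in_trt)))
  }
  list(control_slope = ls_slope(time_h[in_ctrl], concentration[in_ctrl]),
       treatment_slope = ls_slope(time_h[in_trt], concentration[in_trt]))
}

#' Slope fold change with a floored denominator
#'
#' `FC = treatment_slope / max(control_slope, floor)`. The floor is the
#' smallest control-phase production rate distinguishable from no
#' accumulation — by default the analyte's LLOQ divided by the control
#' window duration — and prevents unbounded fold changes when the control
#' slope is near zero or negative; its use is reported via the `floored`
#' flag. Negative treatment slopes are allowed (the resulting FC < 0.5 is a
#' meaningful "decrease").
#'
#' @param control_slope,treatment_slope slopes in pg/mL/h.
#' @param floor positive denominator floor in pg/mL/h.
#' @return list with `fold_change` and `floored`.
#' @export
fold_change <- function(control_slope, treatment_slope, floor) {
  check_scalar(control_slope, "control_slope")
  check_scalar(treatment_slope, "treatment_slope")
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor <= 0) {
    abort("`floor` must be a single positive number")
  }
  floored <- control_slope < floor
  list(fold_change = treatment_slope / max(control_slope, floor),
       floored = floored)
}

#' Default denominator floor for an analyte
#'
#' LLOQ over the control-window duration: a well whose control-phase
#' accumulation never clears the LLOQ has no measurable production rate.
#'
#' @param panel an [analyte_panel()]; `analyte` one of its analytes.
#' @param design a [phase_design()].
#' @return floor in pg/mL/h.
#' @export
default_slope_floor <- function(panel, analyte, design = phase_design()) {
  stopifnot(inherits(panel, "analyte_panel"))
  i <- match(analyte, panel$analyte)
  if (is.na(i)) abort(paste0("analyte not in panel: ", analyte))
  panel$lloq[i] / (design$t_switch - design$t_start)
}

#' Maximum fold change across replicate wells
#'
#' The per-specimen response summary for one analyte: the maximum slope
#' fold change across replicate wells, with the contributing well (first
#' well on ties).
#'
#' @param fc numeric fold changes, one per replicate well (>= 1).
#' @param well_id optional well labels.
#' @return list with `max_fc` and `well_id`.
#' @export
max_fold_change <- function(fc, well_id = seq_along(fc)) {
  if (!length(fc)) abort("need at least one replicate fold change")
  i <- which.max(fc)  # first maximum on ties
  list(max_fc = fc[i], well_id = well_id[i])
}

#' Classify a slope fold change
#'
#' Increase for FC > 1.5, no change for 0.5 <= FC <= 1.5 (both boundaries
#' belong to no change), decrease for FC < 0.5. The three classes partition
#' the whole real line of finite fold changes.
#'
#' @param fc numeric vector of finite fold changes.
#' @return character vector in `increase`, `no_change`, `decrease`.
#' @export
classify_change <- function(fc) {
  if (any(!is.finite(fc))) abort("fold changes must be finite")
  ifelse(fc > 1.5, "increase", ifelse(fc < 0.5, "decrease", "no_change"))
}

#' Concordance between two classification sets
#'
#' Percent of specimen x analyte keys receiving the same class label under
#' two designs (e.g. cross-well vs sequential).
#'
#' @param a,b tibbles with columns `specimen_id`, `analyte`, `class`.
#' @return percent concordant (0-100).
#' @export
concordance <- function(a, b) {
  need <- c("specimen_id", "analyte", "class")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  ka <- paste(a$specimen_id, a$analyte, sep = "\r")
  kb <- paste(b$specimen_id, b$analyte, sep = "\r")
  if (!length(ka) || !length(kb) || !length(intersect(ka, kb))) {
    abort("no shared (specimen, analyte) keys between the two inputs")
  }
  miss_a <- setdiff(kb, ka)
  miss_b <- setdiff(ka, kb)
  if (length(miss_a) || length(miss_b)) {
    abort(paste0("key sets differ; missing from first input: ",
                 toString(gsub("\r", "/", utils::head(miss_a, 5))),
                 "; missing from second: ",
                 toString(gsub("\r", "/", utils::head(miss_b, 5)))))
  }
  100 * mean(a$class == b$class[match(ka, kb)])
}

#' Sequential scoring pipeline
#'
#' For every well x analyte of the chosen treatment arm: per-phase slopes on
#' the actual sample times, the floored slope fold change, a `saturated`
#' flag when any sample in either window was ULOQ-clamped, and the class
#' label; then per specimen x analyte the maximum fold change across
#' replicate wells and its class.
#'
#' @param tbl censored measurement table containing the sequential wells.
#' @param panel an [analyte_panel()] (defines the per-analyte slope floor).
#' @param design a [phase_design()].
#' @param treatment which treatment label to score (default
#'   `"sequential"`).
#' @param drop_below_lloq drop samples flagged `below_lloq` before fitting
#'   (default `FALSE`: censoring retains their values unchanged).
#' @return list of class `sequential_scores`: `wells` (per well x analyte
#'   slopes, FC, flags, class) and `summary` (per specimen x analyte
#'   `max_fc`, contributing well, `class`).
#' @export
score_sequential <- function(tbl, panel, design = phase_design(),
                             treatment = "sequential",
                             drop_below_lloq = FALSE) {
  tbl <- validate_measurements(tbl)
  stopifnot(inherits(panel, "analyte_panel"))
  tbl <- tbl[tbl$treatment %in% treatment, , drop = FALSE]
  if (!nrow(tbl)) abort(paste0("no rows with treatment: ", toString(treatment)))
  if (drop_below_lloq) tbl <- tbl[tbl$censor != "below_lloq", , drop = FALSE]
  floors <- setNames(
    vapply(panel$analyte, default_slope_floor, numeric(1), panel = panel,
           design = design),
    panel$analyte
  )
  wells <- tbl |>
    group_by(.data$specimen_id, .data$well_id, .data$analyte) |>
    group_modify(function(d, key) {
      sl <- phase_slopes(d$time_h, d$concentration_pg_ml, design)
      fc <- fold_change(sl$control_slope, sl$treatment_slope,
                        floors[[key$analyte]])
      tibble(control_slope = sl$control_slope,
             treatment_slope = sl$treatment_slope,
             fold_change = fc$fold_change, floored = fc$floored,
             saturated = any(d$censor == "clamped_uloq"))
    }) |>
    ungroup() |>
    mutate(class = classify_change(.data$fold_change))
  summary <- wells |>
    group_by(.data$specimen_id, .data$analyte) |>
    summarise(
      max_fc = max_fold_change(.data$fold_change, .data$well_id)$max_fc,
      well_id = max_fold_change(.data$fold_change, .data$well_id)$well_id,
      n_wells = dplyr::n(),
      any_floored = any(.data$floored),
      any_saturated = any(.data$saturated),
      .groups = "drop"
    ) |>
    mutate(class = classify_change(.data$max_fc))
  structure(list(wells = wells, summary = summary, design = design),
            class = "sequential_scores")
}
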