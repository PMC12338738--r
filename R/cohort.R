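# Synthetic cytokine cohort generator. Emulates the statistical structure
# the scoring pipelines assume -- per-specimen baseline secretion rates,
# well-level tissue-composition heterogeneity that shrinks with fragment
# count, a treatment-effect multiplier on the post-switch secretion rate,
# multiplicative assay noise, and LOQ censoring -- with full ground truth,
# so both scoring routes can be validated end to end.

#' Configuration for a synthetic cytokine cohort
#'
#' The generative model, per specimen s, well j and analyte a: the
#' cumulative concentration in un-refreshed conditioned media at time t is
#' \deqn{C(t) = r w \min(t, t_s) + m r w \max(t - t_s, 0),}
#' where `r` is the specimen-by-analyte baseline secretion rate (lognormal
#' across the cohort, pg/mL/h), `w` a mean-1 lognormal well-composition
#' multiplier drawn once per well and shared across analytes (composition,
#' not assay noise, drives cross-analyte correlation within a well) with
#' CV = `composition_cv_at_one_fragment / sqrt(fragments_per_well)`,
#' `t_s = switch_time`, and `m` the treatment-effect multiplier applied
#' after the switch. `m > 1` only for responder specimens, responsive
#' analytes and non-control arms; it is 1 for IgG wells, non-responders and
#' non-responsive analytes. Mean-1 multiplicative lognormal noise with CV
#' `noise_cv` is applied independently per sample, then LOQ censoring via
#' `panel`.
#'
#' Responder status depends on biomarker status only through the responder
#' probabilities; baseline rates are biomarker-independent.
#'
#' @param n_specimens number of specimens.
#' @param analytes character vector of analyte names (must be in `panel`).
#' @param responsive_analytes subset of `analytes` whose secretion responds
#'   to treatment in responder specimens.
#' @param biomarker_positive_fraction probability a specimen is
#'   PD-L1/MMR/MSI biomarker-positive.
#' @param responder_prob_given_positive,responder_prob_given_negative
#'   probability of being a functional responder given biomarker status.
#' @param baseline_rate_log_mean,baseline_rate_log_sd meanlog/sdlog of the
#'   lognormal baseline secretion rate r (pg/mL/h) across specimens and
#'   analytes.
#' @param effect_multiplier_range interval (lower >= 1) from which each
#'   responder's per-analyte effect multiplier m is drawn uniformly.
#' @param fragments_per_well fragments pooled into each well.
#' @param composition_cv_at_one_fragment CV of the well-composition
#'   multiplier if a single fragment were plated; pooling n fragments
#'   divides it by sqrt(n).
#' @param noise_cv multiplicative measurement noise CV per sample.
#' @param sample_times media collection times, hours, strictly increasing.
#' @param switch_time control-to-treatment switch, hours; must lie strictly
#'   inside the sampling interval.
#' @param arms treatment arms generated per specimen (subset of
#'   `IgG`, `ICI`, `stim`, `sequential`).
#' @param n_replicate_wells replicate wells per arm.
#' @param panel an [analyte_panel()] used for LOQ censoring.
#' @param seed master integer seed. Child streams per (specimen, well) are
#'   derived by a fixed splitting rule, so enlarging the cohort never
#'   perturbs already-generated specimens.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_specimens = 40,
                          analytes = c("IFN-gamma", "CXCL10", "TNF-alpha",
                                       "IL-2", "CXCL9", "IL-1Ra", "IL-6",
                                       "IL-8", "IL-10", "CCL2"),
                          responsive_analytes = c("IFN-gamma", "CXCL10",
                                                  "TNF-alpha", "IL-2",
                                                  "CXCL9"),
                          biomarker_positive_fraction = 0.4,
                          responder_prob_given_positive = 0.8,
                          responder_prob_given_negative = 0.2,
                          baseline_rate_log_mean = log(5),
                          baseline_rate_log_sd = 0.5,
                          effect_multiplier_range = c(3, 6),
                          fragments_per_well = 200,
                          composition_cv_at_one_fragment = 0.5,
                          noise_cv = 0.1,
                          sample_times = c(4, 20, 48),
                          switch_time = 20,
                          arms = c("IgG", "ICI", "sequential"),
                          n_replicate_wells = 3,
                          panel = default_panel(),
                          seed = 1L) {
  check_scalar(n_specimens, "n_specimens", function(v) v >= 1, "positive")
  stopifnot(inherits(panel, "analyte_panel"))
  analytes <- as.character(analytes)
  if (!length(analytes)) abort("need at least one analyte")
  if (!all(analytes %in% panel$analyte)) {
    abort(paste0("analytes absent from panel: ",
                 toString(setdiff(analytes, panel$analyte))))
  }
  if (!all(responsive_analytes %in% analytes)) {
    abort("`responsive_analytes` must be a subset of `analytes`")
  }
  for (p in c("biomarker_positive_fraction", "responder_prob_given_positive",
              "responder_prob_given_negative")) {
    check_scalar(get(p), p, function(v) v >= 0 && v <= 1, "probability")
  }
  check_scalar(baseline_rate_log_sd, "baseline_rate_log_sd",
               function(v) v >= 0, "non-negative")
  if (length(effect_multiplier_range) != 2L ||
      effect_multiplier_range[1] > effect_multiplier_range[2] ||
      effect_multiplier_range[1] < 1) {
    abort("`effect_multiplier_range` must be an interval with lower bound >= 1")
  }
  check_scalar(fragments_per_well, "fragments_per_well",
               function(v) v >= 1, "positive")
  check_scalar(composition_cv_at_one_fragment, "composition_cv_at_one_fragment",
               function(v) v >= 0, "non-negative")
  check_scalar(noise_cv, "noise_cv", function(v) v >= 0, "non-negative")
  if (length(sample_times) < 2L || any(diff(sample_times) <= 0)) {
    abort("`sample_times` must be strictly increasing with >= 2 points")
  }
  if (switch_time <= min(sample_times) || switch_time >= max(sample_times)) {
    abort("`switch_time` must lie strictly inside the sampling interval")
  }
  arms <- match.arg(arms, TREATMENT_LEVELS, several.ok = TRUE)
  check_scalar(n_replicate_wells, "n_replicate_wells",
               function(v) v >= 1, "positive")
  check_scalar(seed, "seed")
  structure(
    list(n_specimens = as.integer(n_specimens), analytes = analytes,
         responsive_analytes = as.character(responsive_analytes),
         biomarker_positive_fraction = biomarker_positive_fraction,
         responder_prob_given_positive = responder_prob_given_positive,
         responder_prob_given_negative = responder_prob_given_negative,
         baseline_rate_log_mean = baseline_rate_log_mean,
         baseline_rate_log_sd = baseline_rate_log_sd,
         effect_multiplier_range = as.numeric(effect_multiplier_range),
         fragments_per_well = as.integer(fragments_per_well),
         composition_cv_at_one_fragment = composition_cv_at_one_fragment,
         noise_cv = noise_cv, sample_times = as.numeric(sample_times),
         switch_time = switch_time, arms = arms,
         n_replicate_wells = as.integer(n_replicate_wells), panel = panel,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic cytokine cohort with ground truth
#'
#' Draws the cohort described by a [cohort_config()] and returns the
#' censored long-format measurement table together with specimen metadata
#' and the full generating truth (every baseline rate r, well multiplier w,
#' applied effect multiplier m, and responder flag). Deterministic given the
#' config; per-(specimen, well) RNG substreams make the output invariant to
#' cohort enlargement.
#'
#' @param config a [cohort_config()].
#' @return list of class `ltf_cohort` with elements
#'   * `measurements`: censored measurement table ([validate_measurements()]
#'     schema),
#'   * `specimens`: `specimen_id`, `biomarker_status`
#'     (`"positive"`/`"negative"`), `responder`,
#'   * `truth`: per specimen/well/analyte `r`, `w`, `m`, plus flags.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  n_an <- length(cf$analytes)
  times <- cf$sample_times
  n_t <- length(times)
  comp <- lognormal_mean1(
    cf$composition_cv_at_one_fragment / sqrt(cf$fragments_per_well))
  noise <- lognormal_mean1(cf$noise_cv)
  responsive <- cf$analytes %in% cf$responsive_analytes
  wells_per_spec <- tidyr::expand_grid(treatment = cf$arms,
                                       rep = seq_len(cf$n_replicate_wells))
  n_w <- nrow(wells_per_spec)

  spec_rows <- vector("list", cf$n_specimens)
  meas_rows <- vector("list", cf$n_specimens)
  truth_rows <- vector("list", cf$n_specimens)
  withr::local_preserve_seed()  # child streams below leave the caller's RNG intact
  for (i in seq_len(cf$n_specimens)) {
    sid <- sprintf("S%03d", i)
    # specimen-level stream (j = 0): biomarker, responder, rates, multipliers
    set.seed(child_seed(cf$seed, i, 0L))
    positive <- stats::runif(1) < cf$biomarker_positive_fraction
    p_resp <- if (positive) cf$responder_prob_given_positive else
      cf$responder_prob_given_negative
    responder <- stats::runif(1) < p_resp
    r <- stats::rlnorm(n_an, cf$baseline_rate_log_mean, cf$baseline_rate_log_sd)
    m_spec <- rep(1, n_an)
    if (responder) {
      m_spec[responsive] <- stats::runif(sum(responsive),
                                         cf$effect_multiplier_range[1],
                                         cf$effect_multiplier_range[2])
    }
    spec_rows[[i]] <- tibble(
      specimen_id = sid,
      biomarker_status = if (positive) "positive" else "negative",
      responder = responder
    )

    wm <- numeric(n_w)
    eps <- vector("list", n_w)
    for (j in seq_len(n_w)) {
      # well-level stream: composition multiplier + per-sample noise
      set.seed(child_seed(cf$seed, i, j))
      wm[j] <- if (comp$sdlog == 0) 1 else
        stats::rlnorm(1, comp$meanlog, comp$sdlog)
      eps[[j]] <- if (noise$sdlog == 0) {
        matrix(1, n_an, n_t)
      } else {
        matrix(stats::rlnorm(n_an * n_t, noise$meanlog, noise$sdlog), n_an, n_t)
      }
    }

    # assemble this specimen's rows (wells x analytes x times)
    well_id <- sprintf("%s_%s_r%d", sid, wells_per_spec$treatment,
                       wells_per_spec$rep)
    arm_treated <- wells_per_spec$treatment != "IgG"
    pre <- pmin(times, cf$switch_time)
    post <- pmax(times - cf$switch_time, 0)
    blocks <- vector("list", n_w)
    tblocks <- vector("list", n_w)
    for (j in seq_len(n_w)) {
      m_eff <- if (arm_treated[j]) m_spec else rep(1, n_an)
      clean <- outer(r * wm[j], pre) + (m_eff * r * wm[j]) %o% post
      conc <- clean * eps[[j]]
      blocks[[j]] <- tibble(
        specimen_id = sid, well_id = well_id[j],
        treatment = wells_per_spec$treatment[j],
        analyte = rep(cf$analytes, times = n_t),
        time_h = rep(times, each = n_an),
        concentration_pg_ml = as.vector(conc),
        censor = "within"
      )
      tblocks[[j]] <- tibble(
        specimen_id = sid, well_id = well_id[j],
        treatment = wells_per_spec$treatment[j],
        analyte = cf$analytes, r = r, w = wm[j], m = m_eff,
        responder = responder,
        biomarker_status = if (positive) "positive" else "negative"
      )
    }
    meas_rows[[i]] <- dplyr::bind_rows(blocks)
    truth_rows[[i]] <- dplyr::bind_rows(tblocks)
  }

  measurements <- apply_loq(dplyr::bind_rows(meas_rows), cf$panel)
  structure(
    list(measurements = measurements,
         specimens = dplyr::bind_rows(spec_rows),
         truth = dplyr::bind_rows(truth_rows),
         config = cf),
    class = "ltf_cohort"
  )
}

#' @export
print.ltf_cohort <- function(x, ...) {
  cat(sprintf("<ltf_cohort> %d specimens, %d measurement rows, %d analytes\n",
              nrow(x$specimens), nrow(x$measurements),
              length(x$config$analytes)))
  invisible(x)
}
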