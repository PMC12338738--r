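# Cross-well scoring of checkpoint-inhibitor response in resection LTF
# assays: ICI - IgG concentration deltas, MAD-trimmed modified Z-scores
# saturated to [-10, 10], upregulation calls at Z >= 5, Ward clustering of
# the Z matrix, and biomarker enrichment statistics.

#' ICI minus IgG treatment deltas at an endpoint time
#'
#' For every specimen x analyte, the mean cumulative concentration over
#' treated replicate wells at `endpoint_time` minus the mean over control
#' wells at the same time. Wells lacking the endpoint time are excluded with
#' a warning; specimen x analyte cells missing either arm are returned as
#' `NA` with `n_treated`/`n_control` recording the replicates used. Cells
#' where any contributing value was ULOQ-clamped carry `saturated = TRUE`.
#' Below-LLOQ values are retained (censoring keeps them unchanged).
#'
#' @param tbl a censored measurement table (LOQ applied).
#' @param endpoint_time sampling time (hours) at which to take the
#'   cumulative readout; defaults to the latest time in the table.
#' @param control,treated treatment labels of the two arms.
#' @return tibble of class `delta_table`: `specimen_id`, `analyte`, `delta`,
#'   `n_treated`, `n_control`, `saturated`.
#' @export
treatment_delta <- function(tbl, endpoint_time = NULL, control = "IgG",
                            treated = "ICI") {
  tbl <- validate_measurements(tbl)
  tbl <- tbl[tbl$treatment %in% c(control, treated), , drop = FALSE]
  if (!nrow(tbl)) abort("no rows in the control or treated arm")
  if (is.null(endpoint_time)) endpoint_time <- max(tbl$time_h)
  has_ep <- tbl |>
    group_by(.data$well_id) |>
    summarise(ok = any(.data$time_h == endpoint_time), .groups = "drop")
  if (any(!has_ep$ok)) {
    warn(paste0("wells lacking the endpoint time excluded: ",
                toString(utils::head(has_ep$well_id[!has_ep$ok], 5))))
  }
  ep <- tbl[tbl$time_h == endpoint_time, , drop = FALSE]
  arm <- ifelse(ep$treatment == treated, "treated", "control")
  out <- ep |>
    mutate(arm = arm) |>
    group_by(.data$specimen_id, .data$analyte) |>
    summarise(
      delta = mean(.data$concentration_pg_ml[.data$arm == "treated"]) -
        mean(.data$concentration_pg_ml[.data$arm == "control"]),
      n_treated = sum(.data$arm == "treated"),
      n_control = sum(.data$arm == "control"),
      saturated = any(.data$censor == "clamped_uloq"),
      .groups = "drop"
    ) |>
    mutate(delta = ifelse(.data$n_treated == 0 | .data$n_control == 0,
                          NA_real_, .data$delta))
  class(out) <- c("delta_table", class(out))
  out
}

#' MAD-trimmed modified Z-scores of one analyte's deltas
#'
#' The robust standardization used for cross-well scoring, in five steps:
#' (1) `med = median(x)`, `MAD = median(|x - med|)` (raw MAD, no consistency
#' constant); (2) trim to the samples within two MADs of the median
#' (inclusive window); (3) recompute trimmed median `med*` and trimmed MAD
#' `MAD*`; (4) score *all* samples, including trimmed-out ones, as
#' `z = 0.6745 (x - med*) / MAD*`; (5) saturate to `[-10, 10]`. If
#' `MAD* = 0`, the scale falls back to `1.2533 x` the mean absolute
#' deviation of the trimmed set; if that is also zero, all scores are 0.
#'
#' @param x numeric vector of deltas across specimens (>= 3 non-missing).
#' @param saturation length-2 numeric, the lower/upper saturation points.
#' @return list with `z` (same length as `x`, `NA` where `x` is `NA`),
#'   `trimmed_out` (logical), and trimming metadata `median`, `mad`,
#'   `trimmed_median`, `trimmed_mad`, `n_trimmed_out`, `fallback`
#'   (`"none"`, `"mean_ad"` or `"zero"`).
#' @examples
#' mad_trimmed_modified_z(c(1, 2, 3, 4, 100))$z  # outlier saturates at 10
#' @export
mad_trimmed_modified_z <- function(x, saturation = c(-10, 10)) {
  if (length(saturation) != 2L || saturation[1] >= saturation[2]) {
    abort("`saturation` must be an increasing pair")
  }
  ok <- !is.na(x)
  if (sum(ok) < 3L) abort("need at least 3 non-missing values")
  med <- stats::median(x[ok])
  mad0 <- stats::median(abs(x[ok] - med))
  keep <- ok & abs(x - med) <= 2 * mad0
  med_t <- stats::median(x[keep])
  mad_t <- stats::median(abs(x[keep] - med_t))
  fallback <- "none"
  if (mad_t > 0) {
    z <- 0.6745 * (x - med_t) / mad_t
  } else {
    mnad <- mean(abs(x[keep] - med_t))
    if (mnad > 0) {
      fallback <- "mean_ad"
      z <- (x - med_t) / (1.2533 * mnad)
    } else {
      fallback <- "zero"
      z <- ifelse(ok, 0, NA_real_)
    }
  }
  z <- pmin(pmax(z, saturation[1]), saturation[2])
  list(z = z, trimmed_out = ok & !keep, median = med, mad = mad0,
       trimmed_median = med_t, trimmed_mad = mad_t,
       n_trimmed_out = sum(ok) - sum(keep), fallback = fallback)
}

#' Modified Z-score matrix across a cohort
#'
#' Applies [mad_trimmed_modified_z()] per analyte across specimens (each
#' analyte's delta distribution is its own reference, since absolute
#' concentration scales differ by orders of magnitude between cytokines).
#'
#' @param deltas a [treatment_delta()] table.
#' @param saturation saturation points, default `c(-10, 10)`.
#' @return object of class `z_table`: tibble `specimen_id`, `analyte`,
#'   `delta`, `z`, `trimmed_out`, `saturated`; per-analyte trimming metadata
#'   in `attr(, "trim_meta")`.
#' @export
modified_z_matrix <- function(deltas, saturation = c(-10, 10)) {
  stopifnot(all(c("specimen_id", "analyte", "delta") %in% names(deltas)))
  if (!"saturated" %in% names(deltas)) deltas$saturated <- FALSE
  parts <- split(as_tibble(deltas), deltas$analyte)
  meta <- list()
  out <- lapply(names(parts), function(an) {
    d <- parts[[an]]
    res <- mad_trimmed_modified_z(d$delta, saturation)
    meta[[an]] <<- tibble(
      analyte = an, median = res$median, mad = res$mad,
      trimmed_median = res$trimmed_median, trimmed_mad = res$trimmed_mad,
      n_trimmed_out = res$n_trimmed_out, fallback = res$fallback
    )
    tibble(specimen_id = d$specimen_id, analyte = an, delta = d$delta,
           z = res$z, trimmed_out = res$trimmed_out,
           saturated = d$saturated)
  })
  res <- dplyr::bind_rows(out) |> arrange(.data$specimen_id, .data$analyte)
  attr(res, "trim_meta") <- dplyr::bind_rows(meta)
  class(res) <- c("z_table", class(res))
  res
}

#' Upregulation calls from a modified Z matrix
#'
#' The conservative upregulation criterion: an analyte is called upregulated
#' in a specimen when its modified Z-score is greater than or equal to the
#' threshold (inclusive; default 5).
#'
#' @param z a [modified_z_matrix()] table.
#' @param threshold inclusive modified-Z threshold, default 5.
#' @return list of class `upregulation_calls`: `calls` (`specimen_id`,
#'   `analyte`, `upregulated`) and `counts` (`specimen_id`,
#'   `n_upregulated`), plus the `threshold`.
#' @export
call_upregulation <- function(z, threshold = 5) {
  stopifnot(all(c("specimen_id", "analyte", "z") %in% names(z)))
  calls <- tibble(specimen_id = z$specimen_id, analyte = z$analyte,
                  upregulated = !is.na(z$z) & z$z >= threshold)
  counts <- calls |>
    group_by(.data$specimen_id) |>
    summarise(n_upregulated = sum(.data$upregulated), .groups = "drop")
  structure(list(calls = calls, counts = counts, threshold = threshold),
            class = "upregulation_calls")
}

# Sample (cross-product) odds ratio and two-sided Fisher exact p for the
# 2x2 table [[a, b], [c, d]] (rows: upregulated yes/no; cols: biomarker
# +/-). p comes from the standard minimum-likelihood enumeration rule as
# implemented in stats::fisher.test.
fisher_exact_2x2 <- function(a, b, c, d) {
  or <- (a * d) / (b * c)  # Inf when b*c = 0 and a*d > 0; NaN for 0/0
  p <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  list(odds_ratio = or, p_value = p)
}

#' Biomarker enrichment of upregulation calls
#'
#' Two complementary views of whether cytokine upregulation is enriched in
#' the biomarker-positive cohort: (a) per analyte, a 2x2 Fisher exact test
#' of upregulated yes/no against biomarker status, reported with the sample
#' odds ratio; (b) across analytes, a Mann-Whitney rank test (normal
#' approximation with continuity correction) comparing per-specimen
#' upregulated-analyte counts between the two cohorts.
#'
#' @param calls an [call_upregulation()] result.
#' @param meta specimen metadata with columns `specimen_id` and
#'   `biomarker_status` (`"positive"`/`"negative"`); each group needs >= 2
#'   specimens.
#' @return list of class `enrichment_report`: `per_analyte` tibble
#'   (`analyte`, `n_up_pos`, `n_up_neg`, `n_down_pos`, `n_down_neg`,
#'   `odds_ratio`, `p_value`), `count_test` (list with `p_value`,
#'   `statistic`), and `counts` (per-specimen counts joined with status).
#' @export
enrichment <- function(calls, meta) {
  stopifnot(inherits(calls, "upregulation_calls"))
  meta <- as_tibble(meta)
  if (!all(c("specimen_id", "biomarker_status") %in% names(meta))) {
    abort("`meta` needs columns specimen_id and biomarker_status")
  }
  if (!all(meta$biomarker_status %in% c("positive", "negative"))) {
    abort("biomarker_status must be 'positive' or 'negative'")
  }
  df <- calls$calls |> inner_join(meta, by = "specimen_id")
  n_by <- table(factor(unique(df[c("specimen_id", "biomarker_status")])$biomarker_status,
                       levels = c("positive", "negative")))
  if (any(n_by < 2)) {
    abort("each biomarker group needs at least 2 specimens with calls")
  }
  per_analyte <- df |>
    group_by(.data$analyte) |>
    summarise(
      n_up_pos = sum(.data$upregulated & .data$biomarker_status == "positive"),
      n_up_neg = sum(.data$upregulated & .data$biomarker_status == "negative"),
      n_down_pos = sum(!.data$upregulated & .data$biomarker_status == "positive"),
      n_down_neg = sum(!.data$upregulated & .data$biomarker_status == "negative"),
      .groups = "drop"
    )
  ft <- Map(fisher_exact_2x2, per_analyte$n_up_pos, per_analyte$n_up_neg,
            per_analyte$n_down_pos, per_analyte$n_down_neg)
  per_analyte$odds_ratio <- vapply(ft, `[[`, numeric(1), "odds_ratio")
  per_analyte$p_value <- vapply(ft, `[[`, numeric(1), "p_value")

  counts <- calls$counts |> inner_join(meta, by = "specimen_id")
  pos <- counts$n_upregulated[counts$biomarker_status == "positive"]
  neg <- counts$n_upregulated[counts$biomarker_status == "negative"]
  wt <- stats::wilcox.test(pos, neg, exact = FALSE, correct = TRUE)
  # fully tied counts give a 0/0 normal statistic; that is "no evidence"
  if (is.na(wt$p.value)) wt$p.value <- 1
  structure(
    list(per_analyte = per_analyte,
         count_test = list(statistic = unname(wt$statistic),
                           p_value = wt$p.value),
         counts = counts),
    class = "enrichment_report"
  )
}

#' Ward clustering of the modified Z matrix
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances, `stats::hclust(method = "ward.D2")`) applied independently to
#' specimens (rows) and analytes (columns) of the saturated Z matrix.
#' Missing cells are imputed as 0 — the neutral value under the saturation
#' bounds — for clustering only, and their number is reported.
#'
#' @param z a [modified_z_matrix()] table (or any tibble with
#'   `specimen_id`, `analyte`, `z`).
#' @return list of class `z_clustering`: `specimen_hclust`,
#'   `analyte_hclust` (hclust objects), `specimen_order`, `analyte_order`
#'   (leaf labels in dendrogram order), `n_imputed`.
#' @export
cluster_z <- function(z) {
  stopifnot(all(c("specimen_id", "analyte", "z") %in% names(z)))
  wide <- as_tibble(z)[c("specimen_id", "analyte", "z")] |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "z")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$specimen_id
  n_imputed <- sum(is.na(mat))
  mat[is.na(mat)] <- 0
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    abort("clustering needs at least 2 specimens and 2 analytes")
  }
  hr <- stats::hclust(stats::dist(mat), method = "ward.D2")
  hc <- stats::hclust(stats::dist(t(mat)), method = "ward.D2")
  structure(
    list(specimen_hclust = hr, analyte_hclust = hc,
         specimen_order = rownames(mat)[hr$order],
         analyte_order = colnames(mat)[hc$order],
         n_imputed = n_imputed),
    class = "z_clustering"
  )
}

#' Cross-well scoring pipeline
#'
#' Convenience wrapper chaining [treatment_delta()], [modified_z_matrix()],
#' [call_upregulation()], [enrichment()] (when metadata is supplied) and
#' [cluster_z()].
#'
#' @param tbl censored measurement table.
#' @param meta optional specimen metadata (see [enrichment()]).
#' @param endpoint_time endpoint sampling time (hours); default latest.
#' @param z_threshold upregulation threshold on the modified Z (default 5).
#' @param saturation saturation points for the Z-scores.
#' @param cluster whether to cluster (needs >= 2 specimens and analytes).
#' @return list with `deltas`, `z`, `calls`, `enrichment` (or `NULL`),
#'   `clustering` (or `NULL`).
#' @export
score_crosswell <- function(tbl, meta = NULL, endpoint_time = NULL,
                            z_threshold = 5, saturation = c(-10, 10),
                            cluster = TRUE) {
  deltas <- treatment_delta(tbl, endpoint_time)
  z <- modified_z_matrix(deltas, saturation)
  calls <- call_upregulation(z, z_threshold)
  enr <- if (!is.null(meta)) enrichment(calls, meta) else NULL
  cl <- if (isTRUE(cluster)) cluster_z(z) else NULL
  list(deltas = deltas, z = z, calls = calls, enrichment = enr,
       clustering = cl)
}
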