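# Cross-well scoring: deltas, MAD-trimmed modified Z, upregulation calls,
# enrichment statistics, Ward clustering.

test_that("treatment deltas are replicate-mean differences with missingness flags", {
  tbl <- dplyr::bind_rows(
    make_meas("S1", c("i1", "i2"), "ICI", "A", 24, c(50, 60)),
    make_meas("S1", c("g1", "g2"), "IgG", "A", 24, c(20, 20)),
    make_meas("S1", c("i1", "i2"), "ICI", "B", 24, c(30, 30)),
    make_meas("S1", c("g1", "g2"), "IgG", "B", 24, c(30, 30)),
    make_meas("S2", "i1b", "ICI", "A", 24, 40)   # IgG arm missing
  )
  d <- treatment_delta(tbl, endpoint_time = 24)
  expect_equal(d$delta[d$specimen_id == "S1" & d$analyte == "A"], 35)
  expect_equal(d$delta[d$specimen_id == "S1" & d$analyte == "B"], 0)
  expect_true(is.na(d$delta[d$specimen_id == "S2"]))
  expect_false(any(d$saturated))
  # ULOQ-clamped contributions raise the saturation warning flag
  tbl_s <- dplyr::mutate(tbl, censor = ifelse(well_id == "i1" & analyte == "A",
                                              "clamped_uloq", censor))
  d_s <- treatment_delta(tbl_s, endpoint_time = 24)
  expect_true(d_s$saturated[d_s$specimen_id == "S1" & d_s$analyte == "A"])
  # wells lacking the endpoint are excluded with a warning
  tbl_m <- dplyr::bind_rows(tbl, make_meas("S3", "x1", "ICI", "A", 4, 5))
  expect_warning(treatment_delta(tbl_m, endpoint_time = 24), "lacking")
})

test_that("the MAD-trim modified Z follows the five-step procedure", {
  res <- mad_trimmed_modified_z(c(1, 2, 3, 4, 100))
  expect_equal(res$median, 3)
  expect_equal(res$mad, 1)
  expect_equal(res$trimmed_median, 2.5)
  expect_equal(res$trimmed_mad, 1)
  expect_equal(res$n_trimmed_out, 1L)
  expect_equal(res$z, c(-1.01175, -0.33725, 0.33725, 1.01175, 10))
  expect_true(res$trimmed_out[5])
  # constant vector: the fallback chain ends at zero scores
  expect_equal(mad_trimmed_modified_z(rep(4.2, 6))$z, rep(0, 6))
  # location-scale invariance: x -> a x + b (a > 0) leaves z unchanged
  x <- c(-3, 0.5, 1, 2, 7, 11)
  expect_equal(mad_trimmed_modified_z(2.5 * x + 7)$z,
               mad_trimmed_modified_z(x)$z, tolerance = 1e-12)
  expect_error(mad_trimmed_modified_z(c(1, 2)), "at least 3")
})

test_that("vectorised Z-pipeline matches the literal transcription oracle", {
  withr::with_seed(101, {
    for (k in 1:200) {
      n <- sample(3:40, 1)
      x <- switch(sample(3, 1),
                  rnorm(n, 0, 10),
                  rlnorm(n, 2, 1.5),
                  round(rnorm(n), 1))  # ties and zero-MAD cases
      expect_equal(mad_trimmed_modified_z(x)$z, oracle_modified_z(x),
                   tolerance = 0)
    }
  })
})

test_that("raising one specimen's delta never lowers its own Z", {
  withr::with_seed(77, {
    for (k in 1:50) {
      x <- rnorm(12, 0, 5)
      i <- sample(12, 1)
      x2 <- x
      x2[i] <- x[i] + runif(1, 0, 20)
      expect_gte(mad_trimmed_modified_z(x2)$z[i] + 1e-9,
                 mad_trimmed_modified_z(x)$z[i])
    }
  })
})

test_that("upregulation calls use an inclusive threshold", {
  z <- tibble::tibble(specimen_id = c("S1", "S1", "S2", "S2"),
                      analyte = c("A", "B", "A", "B"),
                      z = c(5.0, 4.99, -2, 0))
  calls <- call_upregulation(z, threshold = 5)
  expect_equal(calls$calls$upregulated, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$counts$n_upregulated, c(1L, 0L))
  z0 <- dplyr::mutate(z, z = 0)
  expect_true(all(call_upregulation(z0)$counts$n_upregulated == 0))
})

test_that("Fisher exact matches the enumeration oracle; odds ratio is the cross-product", {
  ft <- ltfscore:::fisher_exact_2x2(8, 1, 2, 9)
  expect_equal(ft$odds_ratio, 36.0)
  expect_equal(ft$p_value, oracle_fisher_p(8, 1, 2, 9), tolerance = 1e-10)
  ft0 <- ltfscore:::fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(ft0$odds_ratio, 1.0)
  expect_equal(ft0$p_value, 1.0)
})

test_that("enrichment reports per-analyte Fisher tests and the count rank test", {
  calls <- call_upregulation(tibble::tibble(
    specimen_id = rep(sprintf("S%02d", 1:10), each = 2),
    analyte = rep(c("A", "B"), 10),
    z = c(rbind(c(rep(8, 5), rep(0, 5)), rep(0, 10)))
  ))
  meta <- tibble::tibble(specimen_id = sprintf("S%02d", 1:10),
                         biomarker_status = rep(c("positive", "negative"),
                                                each = 5))
  rep_ <- enrichment(calls, meta)
  a_row <- rep_$per_analyte[rep_$per_analyte$analyte == "A", ]
  expect_equal(a_row$n_up_pos, 5)
  expect_equal(a_row$n_up_neg, 0)
  expect_equal(a_row$p_value, oracle_fisher_p(5, 0, 0, 5), tolerance = 1e-10)
  expect_lt(rep_$count_test$p_value, 0.05)
  # identical count distributions in both cohorts: null rank test
  calls_null <- call_upregulation(tibble::tibble(
    specimen_id = rep(sprintf("S%02d", 1:10), each = 2),
    analyte = rep(c("A", "B"), 10),
    z = rep(c(8, 0), 10)
  ))
  expect_gte(enrichment(calls_null, meta)$count_test$p_value, 0.99)
  expect_error(enrichment(calls, meta[1:2, ]), "at least 2")
})

test_that("Ward clustering matches a hand-coded agglomeration and separates blocks", {
  # 6 specimens x 4 analytes, two opposite-sign blocks
  withr::with_seed(12, {
    mat <- rbind(matrix(8 + rnorm(12, 0, 0.3), 3, 4),
                 matrix(-8 + rnorm(12, 0, 0.3), 3, 4))
  })
  z <- tibble::tibble(
    specimen_id = rep(sprintf("S%d", 1:6), times = 4),
    analyte = rep(sprintf("a%d", 1:4), each = 6),
    z = as.vector(mat)
  )
  cl <- cluster_z(z)
  expect_equal(sort(cl$specimen_hclust$height),
               sort(oracle_ward_heights(mat)), tolerance = 1e-8)
  ord <- match(sprintf("S%d", 1:6), cl$specimen_order)
  expect_true(max(ord[1:3]) < min(ord[4:6]) || min(ord[1:3]) > max(ord[4:6]))
  # identical rows merge at height zero
  z2 <- z |>
    dplyr::group_by(analyte) |>
    dplyr::mutate(z = ifelse(specimen_id == "S2", z[specimen_id == "S1"], z)) |>
    dplyr::ungroup()
  expect_equal(min(cluster_z(z2)$specimen_hclust$height), 0)
  # permuting input rows leaves the dendrogram topology unchanged
  zp <- z[withr::with_seed(4, sample(nrow(z))), ]
  clp <- cluster_z(zp)
  expect_equal(sort(clp$specimen_hclust$height),
               sort(cl$specimen_hclust$height), tolerance = 1e-10)
  expect_error(cluster_z(z[z$specimen_id == "S1", ]), "at least 2")
})

test_that("missing Z cells are zero-imputed for clustering only, with a count", {
  z <- tidyr::expand_grid(specimen_id = sprintf("S%d", 1:4),
                          analyte = c("A", "B", "C"))
  z$z <- rep(c(5, -5, 0), 4)
  z$z[1] <- NA
  cl <- cluster_z(z)
  expect_equal(cl$n_imputed, 1L)
  expect_equal(length(cl$specimen_order), 4)
})
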