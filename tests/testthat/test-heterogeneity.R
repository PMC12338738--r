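# Partitioning, randomized pooling, and design comparison.

test_that("fragment geometry arithmetic is exact", {
  g <- fragment_geometry(1000)
  expect_equal(g$volume_mm3, 1.0)
  expect_equal(g$face_area_mm2, 1.0)
  expect_error(fragment_geometry(-1), "positive")
  expect_error(fragment_geometry(300, -2), "non-negative")
})

test_that("partition tiles the domain and conserves cell counts", {
  empty <- cell_map(3000, 3000)
  fr <- partition_map(empty, fragmentation_scheme("cuboid", 300))
  expect_equal(length(unique(fr$fragment_id)), 100)
  expect_true(all(fr$count == 0))

  one <- cell_map(3000, 3000, tibble::tibble(x_um = 150, y_um = 150,
                                             marker = "CD3"))
  fr1 <- partition_map(one, fragmentation_scheme("cuboid", 300))
  expect_equal(sum(fr1$count), 1)
  expect_equal(sum(fr1$count > 0), 1)
  expect_equal(fr1$fragment_id[fr1$count == 1], 1L)

  withr::with_seed(5, {
    cells <- tibble::tibble(x_um = runif(10000, 0, 3000),
                            y_um = runif(10000, 0, 3000), marker = "CD3")
  })
  map <- cell_map(3000, 3000, cells)
  fr2 <- partition_map(map, fragmentation_scheme("cuboid", 300))
  expect_equal(length(unique(fr2$fragment_id)), 100)
  # direct counting oracle: every cell lies in exactly one full fragment here
  expect_equal(sum(fr2$count), 10000)
  oracle <- mapply(function(x0, x1, y0, y1) {
    sum(cells$x_um >= x0 & cells$x_um < x1 &
          cells$y_um >= y0 & cells$y_um < y1)
  }, fr2$xmin, fr2$xmax, fr2$ymin, fr2$ymax)
  expect_equal(fr2$count, as.integer(oracle))
  expect_lt(abs(mean(fr2$count) - 100), 4 * sqrt(100 / 100) * 10)
})

test_that("partition uses half-open intervals and discards partial fragments", {
  cells <- tibble::tibble(x_um = c(0, 299.999, 300, 2999.9),
                          y_um = c(0, 0, 0, 2999.9), marker = "CD3")
  map <- cell_map(3000, 3000, cells)
  fr <- partition_map(map, fragmentation_scheme("cuboid", 300))
  # cell at exactly 300 falls in the second column, not the first
  expect_equal(fr$count[fr$fragment_id == 1], 2L)
  expect_equal(fr$count[fr$fragment_id == 2], 1L)
  # 3100 um domain with 300 um grid: the partial boundary row/col is dropped
  map2 <- cell_map(3100, 3100, tibble::tibble(x_um = 3050, y_um = 50,
                                              marker = "CD3"))
  fr2 <- partition_map(map2, fragmentation_scheme("cuboid", 300))
  expect_equal(length(unique(fr2$fragment_id)), 100)
  expect_equal(sum(fr2$count), 0)  # the cell sits in a discarded partial strip
  # partition is invariant to cell ordering
  shuf <- cell_map(3000, 3000, cells[c(3, 1, 4, 2), ])
  expect_identical(partition_map(shuf, fragmentation_scheme("cuboid", 300)),
                   fr)
  expect_warning(
    fr3 <- partition_map(map, fragmentation_scheme("cuboid", 5000)),
    "no full fragments")
  expect_equal(nrow(fr3), 0)
})

test_that("slice mode returns full-height strips", {
  cells <- tibble::tibble(x_um = c(100, 100, 500), y_um = c(10, 2900, 1500),
                          marker = "CD3")
  map <- cell_map(3000, 3000, cells)
  fr <- partition_map(map, fragmentation_scheme("slice", 300))
  expect_equal(length(unique(fr$fragment_id)), 10)
  expect_true(all(fr$ymin == 0 & fr$ymax == 3000))
  expect_equal(fr$count[fr$fragment_id == 1], 2L)
  expect_equal(fr$count[fr$fragment_id == 2], 1L)
})

test_that("pooling of homogeneous fragments has zero CV; degenerate cases flagged", {
  fr <- tibble::tibble(fragment_id = 1:20, marker = "CD3", count = 7L)
  pr <- simulate_pooling(fr, "CD3", pool_size = 5, n_pools = 50, seed = 1)
  expect_equal(pr$cv_percent, 0)
  expect_true(all(pr$per_pool_counts == 35))
  # exhaustive pooling: every pool is the whole tissue
  pr2 <- simulate_pooling(fr, "CD3", pool_size = 20, n_pools = 5, seed = 1)
  expect_equal(pr2$cv_percent, 0)
  # all-zero counts: CV undefined, flagged rather than infinite
  fr0 <- tibble::tibble(fragment_id = 1:10, marker = "CD3", count = 0L)
  pr0 <- simulate_pooling(fr0, "CD3", pool_size = 2, n_pools = 10, seed = 1)
  expect_true(is.na(pr0$cv_percent))
  expect_false(pr0$cv_defined)
  expect_error(simulate_pooling(fr, "CD3", pool_size = 21, n_pools = 5),
               "exceeds")
})

test_that("pooling is deterministic given the seed and CV is scale-free", {
  withr::with_seed(8, {
    fr <- tibble::tibble(fragment_id = 1:100, marker = "CD3",
                         count = rpois(100, 30))
  })
  a <- simulate_pooling(fr, "CD3", 10, 200, seed = 5)
  b <- simulate_pooling(fr, "CD3", 10, 200, seed = 5)
  expect_identical(a$per_pool_counts, b$per_pool_counts)
  fr_k <- dplyr::mutate(fr, count = count * 17L)
  ck <- simulate_pooling(fr_k, "CD3", 10, 200, seed = 5)
  expect_equal(ck$cv_percent, a$cv_percent, tolerance = 1e-12)
  expect_equal(ck$mean_count, 17 * a$mean_count)
})

test_that("on a homogeneous map all fragmentation designs agree at matched pooled area", {
  map <- generate_cell_map(map_config(6000, 6000, background_intensity = 800,
                                      cluster_parent_intensity = 0, seed = 31))
  tab <- compare_designs(
    map,
    list(fragmentation_scheme("slice", 300),
         fragmentation_scheme("cuboid", 300),
         fragmentation_scheme("cuboid", 100)),
    pool_sizes = 2, n_pools = 600, seed = 17, n_perm = 199
  )
  expect_equal(nrow(tab), 3)
  expect_equal(unique(round(tab$pooled_area_mm2, 6)), 3.6)
  # Poisson closed form holds for every scheme: geometry alone changes
  # nothing. Pools are drawn without replacement, so the exact CV carries a
  # finite-population factor sqrt(1 - n/N); the Monte-Carlo SE combines the
  # pool-resampling term and the realized-population term.
  for (i in seq_len(nrow(tab))) {
    expected <- 800 * tab$pooled_area_mm2[i]
    frac <- tab$pool_size[i] / tab$n_fragments[i]
    theo <- 100 / sqrt(expected) * sqrt(1 - frac)
    se <- theo * sqrt(1 / (2 * tab$n_fragments[i]) + 1 / (2 * 600))
    expect_lt(abs(tab$cv_percent[i] - theo), 3 * se)
  }
  # and the dispersion permutation test sees no slice-vs-cuboid difference
  expect_true(all(tab$p_vs_slice[tab$mode == "cuboid"] > 0.05))
})

test_that("compare_designs with a single scheme delegates to simulate_pooling", {
  map <- generate_cell_map(map_config(3000, 3000, background_intensity = 300,
                                      cluster_parent_intensity = 0, seed = 2))
  sc <- fragmentation_scheme("cuboid", 300)
  tab <- compare_designs(map, list(sc), pool_sizes = 10, n_pools = 100,
                         seed = 4, n_perm = 0)
  fr <- partition_map(map, sc)
  # same child seed as compare_designs uses for (scheme 1, pool size 1)
  pr <- simulate_pooling(fr, "CD3", 10, 100,
                         seed = ltfscore:::child_seed(4, 1, 1))
  expect_equal(tab$cv_percent, pr$cv_percent)
  expect_equal(tab$mean_count, pr$mean_count)
})
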