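# Fragmentation and randomized-pooling simulation: how cutting geometry and
# pool size control the sampling variability of marker-positive cell counts
# across wells.

#' Define a fragmentation scheme
#'
#' Either `cuboid` (a square grid of fragments with the given edge length;
#' the in-plane footprint of cuboid live tumor fragments) or `slice` (full
#' domain-height strips of the given thickness along x, the footprint of a
#' standard slice sampling technique).
#'
#' @param mode `"cuboid"` or `"slice"`.
#' @param size_um edge length (cuboid) or slice thickness (slice), in
#'   micrometres (> 0).
#' @param origin numeric length-2, the lower-left corner of the grid in
#'   micrometres (components >= 0).
#' @return object of class `fragmentation_scheme`.
#' @export
fragmentation_scheme <- function(mode = c("cuboid", "slice"), size_um,
                                 origin = c(0, 0)) {
  mode <- match.arg(mode)
  check_scalar(size_um, "size_um", function(v) v > 0, "positive")
  if (length(origin) != 2L || any(!is.finite(origin)) || any(origin < 0)) {
    abort("`origin` must be two non-negative coordinates")
  }
  structure(list(mode = mode, size_um = size_um, origin = as.numeric(origin)),
            class = "fragmentation_scheme")
}

scheme_label <- function(scheme) {
  sprintf("%s_%g", scheme$mode, scheme$size_um)
}

# Footprint area of one fragment, mm2 (slices span the full domain height).
scheme_fragment_area_mm2 <- function(scheme, map) {
  if (scheme$mode == "cuboid") (scheme$size_um / 1000)^2
  else (scheme$size_um / 1000) * (map$domain_height / 1000)
}

#' Partition a cell map into fragments
#'
#' Cells are assigned to fragments by half-open intervals
#' `[lo, lo + size)`, so no cell is counted twice and boundary behavior is
#' exact. Only full-size fragments entirely inside the domain are returned;
#' partial boundary fragments are discarded (pools must consist of
#' equal-volume fragments). Slice mode returns full-height strips.
#'
#' @param map a [cell_map()].
#' @param scheme a [fragmentation_scheme()].
#' @param markers markers to count; defaults to the markers present on the
#'   map (a single `NA` placeholder for an empty map, so the fragment grid is
#'   still returned).
#' @return tibble with one row per fragment x marker: `fragment_id`, `row`,
#'   `col`, `xmin`, `xmax`, `ymin`, `ymax`, `marker`, `count`. Zero fragments
#'   (scheme larger than the domain) yields an empty tibble with a warning.
#' @export
partition_map <- function(map, scheme, markers = NULL) {
  stopifnot(inherits(map, "cell_map"), inherits(scheme, "fragmentation_scheme"))
  if (is.null(markers)) {
    markers <- sort(unique(map$cells$marker))
    if (!length(markers)) markers <- NA_character_
  }
  e <- scheme$size_um
  ox <- scheme$origin[1]
  oy <- scheme$origin[2]
  n_x <- floor((map$domain_width - ox) / e)
  if (scheme$mode == "cuboid") {
    n_y <- floor((map$domain_height - oy) / e)
  } else {
    n_y <- if (oy == 0) 1L else 0L  # slices must span the full height
  }
  if (n_x < 1L || n_y < 1L) {
    warn(paste0("scheme ", scheme_label(scheme),
                " produces no full fragments on this domain"))
    return(tibble(fragment_id = integer(), row = integer(), col = integer(),
                  xmin = numeric(), xmax = numeric(), ymin = numeric(),
                  ymax = numeric(), marker = character(), count = integer()))
  }
  grid <- tidyr::expand_grid(row = seq_len(n_y), col = seq_len(n_x))
  grid$fragment_id <- seq_len(nrow(grid))
  grid$xmin <- ox + (grid$col - 1L) * e
  grid$xmax <- grid$xmin + e
  if (scheme$mode == "cuboid") {
    grid$ymin <- oy + (grid$row - 1L) * e
    grid$ymax <- grid$ymin + e
  } else {
    grid$ymin <- 0
    grid$ymax <- map$domain_height
  }

  cells <- map$cells
  counts <- tibble(fragment_id = integer(), marker = character(),
                   n = integer())
  if (nrow(cells)) {
    cx <- floor((cells$x_um - ox) / e)
    if (scheme$mode == "cuboid") {
      cy <- floor((cells$y_um - oy) / e)
    } else {
      cy <- ifelse(cells$y_um >= 0, 0, -1)
    }
    ok <- cells$x_um >= ox & cx >= 0 & cx < n_x & cy >= 0 & cy < n_y &
      (scheme$mode == "slice" | cells$y_um >= oy)
    fid <- cy[ok] * n_x + cx[ok] + 1L
    if (any(ok)) {
      counts <- tibble(fragment_id = as.integer(fid),
                       marker = cells$marker[ok]) |>
        dplyr::count(.data$fragment_id, .data$marker)
    }
  }
  out <- tidyr::expand_grid(fragment_id = grid$fragment_id, marker = markers) |>
    left_join(counts, by = c("fragment_id", "marker")) |>
    mutate(count = ifelse(is.na(.data$n), 0L, .data$n)) |>
    select(-"n") |>
    left_join(grid, by = "fragment_id") |>
    select("fragment_id", "row", "col", "xmin", "xmax", "ymin", "ymax",
           "marker", "count") |>
    arrange(.data$fragment_id, .data$marker)
  out
}

#' Simulate randomized pooling of fragments into wells
#'
#' Each pool (well) is an independent uniform random sample of `pool_size`
#' fragments drawn without replacement; its count is the sum of the chosen
#' fragments' marker counts. The dispersion of pool counts, expressed as a
#' CV%, measures how well randomized pooling suppresses tissue-composition
#' sampling noise.
#'
#' @param fragments output of [partition_map()].
#' @param marker which marker's counts to pool (default: the single marker
#'   present).
#' @param pool_size fragments per pool (<= number of fragments).
#' @param n_pools number of independently re-randomized pools.
#' @param seed integer RNG seed.
#' @return object of class `pooling_result`: a list with `pool_size`,
#'   `n_pools`, `marker`, `per_pool_counts`, `mean_count`, `cv_percent`
#'   (sample SD / mean x 100; `NA` with `cv_defined = FALSE` when the mean
#'   pool count is zero).
#' @export
simulate_pooling <- function(fragments, marker = NULL, pool_size, n_pools,
                             seed = 1L) {
  if (is.null(marker)) {
    marker <- unique(fragments$marker)
    if (length(marker) != 1L) {
      abort("`marker` must be given when fragments carry several markers")
    }
  }
  counts <- fragments$count[fragments$marker %in% marker]
  n_frag <- length(counts)
  check_scalar(pool_size, "pool_size", function(v) v >= 1, "positive")
  check_scalar(n_pools, "n_pools", function(v) v >= 1, "positive")
  if (pool_size > n_frag) {
    abort(sprintf("pool_size (%d) exceeds the number of fragments (%d)",
                  pool_size, n_frag))
  }
  totals <- withr::with_seed(seed, {
    vapply(seq_len(n_pools), function(i) {
      sum(counts[sample.int(n_frag, pool_size, replace = FALSE)])
    }, numeric(1))
  })
  m <- mean(totals)
  cv <- if (m == 0) NA_real_ else cv_percent(totals)
  structure(
    list(pool_size = as.integer(pool_size), n_pools = as.integer(n_pools),
         marker = marker, per_pool_counts = totals, mean_count = m,
         cv_percent = cv, cv_defined = m > 0),
    class = "pooling_result"
  )
}

#' @export
print.pooling_result <- function(x, ...) {
  cat(sprintf("<pooling_result> %d pools of %d fragments (%s): mean %.1f, CV %.2f%%\n",
              x$n_pools, x$pool_size, x$marker, x$mean_count, x$cv_percent))
  invisible(x)
}

#' Compare fragmentation designs at matched pooled tissue
#'
#' Runs [partition_map()] and [simulate_pooling()] for every combination of
#' scheme and pool size and tabulates the pool-count CV. With
#' `match_area = TRUE` (default) the entries of `pool_sizes` are fragments
#' per pool for the *first* scheme; every other scheme's pool size is
#' rescaled by fragment footprint area so all schemes pool the same amount
#' of tissue — the comparison the slice-versus-cuboid analysis requires.
#' When a slice scheme is present, each cuboid scheme is additionally
#' compared to it by a two-sample permutation test on pool-count dispersion
#' (counts normalized by their group mean; statistic = difference of sample
#' CVs; labels permuted).
#'
#' @param map a [cell_map()].
#' @param schemes list of [fragmentation_scheme()]s.
#' @param pool_sizes integer vector (interpreted for the first scheme when
#'   `match_area = TRUE`).
#' @param n_pools pools per combination.
#' @param seed integer RNG seed.
#' @param marker marker to count (default: the map's single marker).
#' @param match_area rescale pool sizes to equal pooled area per scheme.
#' @param n_perm permutation-test resamples (0 skips the test, `p_vs_slice`
#'   is then `NA`).
#' @return tibble with one row per scheme x pool size: `scheme`, `mode`,
#'   `size_um`, `pool_size`, `pooled_area_mm2`, `n_fragments`, `mean_count`,
#'   `cv_percent`, `p_vs_slice`.
#' @export
compare_designs <- function(map, schemes, pool_sizes, n_pools = 500,
                            seed = 1L, marker = NULL, match_area = TRUE,
                            n_perm = 999) {
  stopifnot(inherits(map, "cell_map"), length(schemes) >= 1L)
  if (inherits(schemes, "fragmentation_scheme")) schemes <- list(schemes)
  areas <- vapply(schemes, scheme_fragment_area_mm2, numeric(1), map = map)
  ref_area <- areas[[1]]
  rows <- list()
  pools <- list()
  for (si in seq_along(schemes)) {
    sc <- schemes[[si]]
    frags <- partition_map(map, sc)
    if (!nrow(frags)) next
    if (is.null(marker)) marker <- unique(frags$marker)[1]
    n_frag <- length(unique(frags$fragment_id))
    for (pi in seq_along(pool_sizes)) {
      ps <- if (match_area) {
        max(1L, as.integer(round(pool_sizes[pi] * ref_area / areas[[si]])))
      } else as.integer(pool_sizes[pi])
      if (ps > n_frag) {
        warn(sprintf("skipping %s at pool size %d (> %d fragments)",
                     scheme_label(sc), ps, n_frag))
        next
      }
      pr <- simulate_pooling(frags, marker, ps, n_pools,
                             seed = child_seed(seed, si, pi))
      key <- paste(scheme_label(sc), pi, sep = ".")
      pools[[key]] <- pr
      rows[[key]] <- tibble(
        scheme = scheme_label(sc), mode = sc$mode, size_um = sc$size_um,
        pool_index = pi, pool_size = pr$pool_size,
        pooled_area_mm2 = pr$pool_size * areas[[si]],
        n_fragments = n_frag, mean_count = pr$mean_count,
        cv_percent = pr$cv_percent
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_vs_slice <- NA_real_
  slice_rows <- which(out$mode == "slice")
  if (n_perm > 0 && length(slice_rows)) {
    for (i in seq_len(nrow(out))) {
      if (out$mode[i] != "cuboid") next
      j <- slice_rows[match(out$pool_index[i], out$pool_index[slice_rows])]
      if (is.na(j)) next
      a <- pools[[paste(out$scheme[j], out$pool_index[j], sep = ".")]]$per_pool_counts
      b <- pools[[paste(out$scheme[i], out$pool_index[i], sep = ".")]]$per_pool_counts
      out$p_vs_slice[i] <- permutation_cv_test(
        a, b, n_perm, seed = child_seed(seed, 7919L, i))
    }
  }
  out$pool_index <- NULL
  out
}

# Two-sided permutation test for unequal dispersion of two samples of pool
# counts. Counts are normalized by their own group mean (removing the scale
# difference between designs); the statistic is the difference of sample
# CVs, and group labels are permuted.
permutation_cv_test <- function(a, b, n_perm = 999, seed = 1L) {
  xa <- a / mean(a)
  xb <- b / mean(b)
  stat <- function(u, v) abs(cv_percent(u) - cv_percent(v))
  obs <- stat(xa, xb)
  if (is.na(obs)) return(NA_real_)
  pooled <- c(xa, xb)
  na <- length(xa)
  withr::with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(length(pooled), na)
      stat(pooled[idx], pooled[-idx])
    }, numeric(1))
  })
  (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1)
}

#' Fragment geometry arithmetic
#'
#' Face area and volume of a cuboid fragment of the given edge length, and
#' the total volume of `n_fragments` such fragments. A 300 um edge gives a
#' face area of 0.09 mm2 and a volume of 0.027 mm3; 200 fragments total
#' 5.4 mm3.
#'
#' @param edge_um cuboid edge length in micrometres (> 0).
#' @param n_fragments number of fragments (>= 0, default 1).
#' @return tibble with `edge_um`, `face_area_mm2`, `volume_mm3`,
#'   `n_fragments`, `total_volume_mm3`.
#' @export
fragment_geometry <- function(edge_um, n_fragments = 1) {
  check_scalar(edge_um, "edge_um", function(v) v > 0, "positive")
  check_scalar(n_fragments, "n_fragments", function(v) v >= 0, "non-negative")
  e_mm <- edge_um / 1000
  tibble(
    edge_um = edge_um,
    face_area_mm2 = e_mm^2,
    volume_mm3 = e_mm^3,
    n_fragments = n_fragments,
    total_volume_mm3 = n_fragments * e_mm^3
  )
}
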