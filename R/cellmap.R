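# 2D marker-labeled cell maps: the substrate for fragmentation and pooling
# simulations. Maps are either imported from segmentation output or
# simulated as Poisson background + Thomas cluster process.

#' Construct a cell map
#'
#' A cell map is a rectangular tissue domain (widths in micrometres) with a
#' table of marker-labeled cell coordinates, e.g. CD3+ centroids from a
#' segmented IHC section.
#'
#' @param domain_width,domain_height domain size in micrometres (> 0).
#' @param cells tibble/data frame with columns `x_um`, `y_um`, `marker`;
#'   coordinates must satisfy `0 <= x < domain_width`,
#'   `0 <= y < domain_height`.
#' @return object of class `cell_map`.
#' @export
cell_map <- function(domain_width, domain_height,
                     cells = tibble(x_um = numeric(), y_um = numeric(),
                                    marker = character())) {
  check_scalar(domain_width, "domain_width", function(v) v > 0, "positive")
  check_scalar(domain_height, "domain_height", function(v) v > 0, "positive")
  cells <- as_tibble(cells)
  need <- c("x_um", "y_um", "marker")
  miss <- setdiff(need, names(cells))
  if (length(miss)) abort(paste0("cells table missing columns: ", toString(miss)))
  cells <- cells[need]
  if (nrow(cells)) {
    ok <- cells$x_um >= 0 & cells$x_um < domain_width &
      cells$y_um >= 0 & cells$y_um < domain_height
    if (!all(ok)) abort("cell coordinates must lie inside the domain")
  }
  structure(
    list(domain_width = domain_width, domain_height = domain_height,
         cells = cells),
    class = "cell_map"
  )
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %.0f x %.0f um, %d cells (%s)\n",
              x$domain_width, x$domain_height, nrow(x$cells),
              toString(unique(x$cells$marker))))
  invisible(x)
}

#' Configuration for a simulated cell map
#'
#' Describes a synthetic marker-positive cell distribution: a homogeneous
#' Poisson background superposed with a Thomas cluster process (Poisson
#' parents, Poisson-distributed offspring counts, isotropic Gaussian
#' offspring displacement). This emulates the clustered T-cell distributions
#' seen in stained tumor sections, which drive sampling noise when tissue is
#' divided into fragments.
#'
#' @param domain_width,domain_height domain size in micrometres (> 0).
#' @param background_intensity homogeneous background intensity, cells/mm2.
#' @param cluster_parent_intensity cluster-center intensity, parents/mm2.
#' @param cluster_mean_offspring mean cells per cluster (>= 0).
#' @param cluster_sigma isotropic Gaussian displacement SD, micrometres.
#' @param marker_label marker name attached to every cell.
#' @param seed integer RNG seed; maps are deterministic given the config.
#' @return object of class `map_config`.
#' @export
map_config <- function(domain_width = 6000, domain_height = 6000,
                       background_intensity = 30,
                       cluster_parent_intensity = 2,
                       cluster_mean_offspring = 60,
                       cluster_sigma = 150,
                       marker_label = "CD3", seed = 1L) {
  check_scalar(domain_width, "domain_width", function(v) v > 0, "positive")
  check_scalar(domain_height, "domain_height", function(v) v > 0, "positive")
  check_scalar(background_intensity, "background_intensity",
               function(v) v >= 0, "non-negative")
  check_scalar(cluster_parent_intensity, "cluster_parent_intensity",
               function(v) v >= 0, "non-negative")
  check_scalar(cluster_mean_offspring, "cluster_mean_offspring",
               function(v) v >= 0, "non-negative")
  check_scalar(cluster_sigma, "cluster_sigma", function(v) v > 0, "positive")
  check_scalar(seed, "seed")
  structure(
    list(domain_width = domain_width, domain_height = domain_height,
         background_intensity = background_intensity,
         cluster_parent_intensity = cluster_parent_intensity,
         cluster_mean_offspring = cluster_mean_offspring,
         cluster_sigma = cluster_sigma,
         marker_label = as.character(marker_label),
         seed = as.integer(seed)),
    class = "map_config"
  )
}

#' Simulate a cell map (Poisson background + Thomas cluster process)
#'
#' Cells are the union of a homogeneous Poisson process at
#' `background_intensity` and a Thomas process: parents are Poisson at
#' `cluster_parent_intensity` on the domain extended by 4 cluster sigmas on
#' every side (edge correction, so clusters centred just outside the section
#' still contribute), each parent gets a Poisson(`cluster_mean_offspring`)
#' number of offspring displaced by an isotropic Gaussian with SD
#' `cluster_sigma`, and offspring falling outside the domain are discarded.
#'
#' @param config a [map_config()].
#' @return a [cell_map()]; identical for identical configs.
#' @export
generate_cell_map <- function(config) {
  stopifnot(inherits(config, "map_config"))
  W <- config$domain_width
  H <- config$domain_height
  withr::with_seed(config$seed, {
    area_mm2 <- W * H / 1e6
    n_bg <- stats::rpois(1L, config$background_intensity * area_mm2)
    x <- stats::runif(n_bg, 0, W)
    y <- stats::runif(n_bg, 0, H)
    pad <- 4 * config$cluster_sigma
    ext_area_mm2 <- (W + 2 * pad) * (H + 2 * pad) / 1e6
    n_par <- stats::rpois(1L, config$cluster_parent_intensity * ext_area_mm2)
    if (n_par > 0) {
      px <- stats::runif(n_par, -pad, W + pad)
      py <- stats::runif(n_par, -pad, H + pad)
      n_off <- stats::rpois(n_par, config$cluster_mean_offspring)
      if (sum(n_off) > 0) {
        cx <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, config$cluster_sigma)
        cy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, config$cluster_sigma)
        keep <- cx >= 0 & cx < W & cy >= 0 & cy < H
        x <- c(x, cx[keep])
        y <- c(y, cy[keep])
      }
    }
  })
  cell_map(W, H, tibble(x_um = x, y_um = y,
                        marker = rep(config$marker_label, length(x))))
}

#' Read / write a cell map as delimited text
#'
#' Columns `x_um,y_um,marker`; the domain size is carried in a `#`-prefixed
#' header comment (`# domain_um: <width> <height>`). When the comment is
#' absent on read, the domain defaults to the ceiling of the largest
#' coordinate in each axis.
#'
#' @param map a [cell_map()]; `path` a file path.
#' @return [read_cell_map()] returns a [cell_map()];
#'   [write_cell_map()] returns `path` invisibly.
#' @export
write_cell_map <- function(map, path) {
  stopifnot(inherits(map, "cell_map"))
  writeLines(c(sprintf("# domain_um: %.6g %.6g", map$domain_width,
                       map$domain_height),
               sub("\n$", "", readr::format_csv(map$cells))),
             path)
  invisible(path)
}

#' @rdname write_cell_map
#' @export
read_cell_map <- function(path) {
  if (!file.exists(path)) abort(paste0("cell map file not found: ", path))
  first <- readLines(path, n = 1L)
  dom <- NULL
  if (grepl("^#\\s*domain_um:", first)) {
    dom <- as.numeric(strsplit(sub("^#\\s*domain_um:\\s*", "", first),
                               "\\s+")[[1]])
  }
  cells <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    x_um = readr::col_double(), y_um = readr::col_double(),
    marker = readr::col_character()
  ), progress = FALSE)
  if (is.null(dom) || length(dom) != 2L || any(!is.finite(dom))) {
    dom <- c(floor(max(cells$x_um, 0)) + 1, floor(max(cells$y_um, 0)) + 1)
  }
  cell_map(dom[1], dom[2], cells)
}
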