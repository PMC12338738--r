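#' Define a multiplex analyte panel with quantitation limits
#'
#' A panel records, for every analyte in a multiplex cytokine kit, the lower
#' and upper limits of quantitation (LLOQ/ULOQ, pg/mL) and which analytes are
#' excluded from analysis. All censoring decisions downstream
#' ([apply_loq()], QC denominators, slope floors) are governed by the panel.
#'
#' @param analyte character vector of analyte names (unique).
#' @param lloq,uloq numeric vectors (recycled if length 1) of lower/upper
#'   limits of quantitation in pg/mL; `lloq` must be positive and strictly
#'   below `uloq` for every analyte.
#' @param excluded character vector of analyte names to drop from all
#'   analysis (must be a subset of `analyte`).
#' @return A tibble of class `analyte_panel` with columns `analyte`, `lloq`,
#'   `uloq`, `excluded` (logical).
#' @examples
#' analyte_panel(c("IFN-gamma", "CXCL10", "EGF"),
#'               lloq = 2, uloq = 1e4, excluded = "EGF")
#' @export
analyte_panel <- function(analyte, lloq, uloq, excluded = character()) {
  if (anyDuplicated(analyte)) abort("panel analyte names must be unique")
  n <- length(analyte)
  if (n == 0L) abort("panel must contain at least one analyte")
  lloq <- rep_len(as.numeric(lloq), n)
  uloq <- rep_len(as.numeric(uloq), n)
  if (any(!is.finite(lloq)) || any(!is.finite(uloq)) || any(lloq <= 0)) {
    abort("`lloq` and `uloq` must be finite and `lloq` positive")
  }
  if (any(lloq >= uloq)) abort("every analyte needs `lloq` < `uloq`")
  bad <- setdiff(excluded, analyte)
  if (length(bad)) {
    abort(paste0("excluded analytes not in panel: ", toString(bad)))
  }
  out <- tibble(
    analyte = as.character(analyte), lloq = lloq, uloq = uloq,
    excluded = analyte %in% excluded
  )
  class(out) <- c("analyte_panel", class(out))
  out
}

#' Analytes retained by a panel (exclusions removed)
#' @param panel an [analyte_panel()].
#' @return character vector of analyte names.
#' @export
panel_analytes <- function(panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  panel$analyte[!panel$excluded]
}

#' A default 36-analyte cytokine panel
#'
#' Emulates a human XL cytokine multiplex kit: 36 analytes of which six
#' (CD40L, EGF, FGF basic, IL-12p70, IL-15, FLT-3L) are excluded for
#' consistently unquantifiable concentrations, leaving a 30-cytokine working
#' panel. Kits do not publish a single set of limits valid for every lot, so
#' nominal limits (LLOQ 2 pg/mL, ULOQ 10,000 pg/mL) are used; pass a
#' kit-specific panel for real data.
#'
#' @return an [analyte_panel()].
#' @export
default_panel <- function() {
  retained <- c(
    "IFN-gamma", "CXCL10", "IL-1Ra", "TNF-alpha", "IL-2", "IL-6", "CXCL9",
    "IL-10", "GM-CSF", "IL-8", "IL-4", "IL-5", "IL-7", "IL-13", "IL-17A",
    "IL-1alpha", "IL-1beta", "IL-33", "CCL2", "CCL3", "CCL4", "CCL5",
    "CCL11", "CXCL1", "CXCL2", "G-CSF", "TRAIL", "VEGF", "PDGF-BB",
    "Granzyme-B"
  )
  excluded <- c("CD40L", "EGF", "FGF basic", "IL-12p70", "IL-15", "FLT-3L")
  analyte_panel(c(retained, excluded), lloq = 2, uloq = 1e4,
                excluded = excluded)
}

#' Read / write an analyte panel
#'
#' Delimited text with header `analyte,lloq,uloq,excluded` (excluded as
#' TRUE/FALSE), or a JSON file with those fields.
#'
#' @param path file path; `.json` extension selects JSON.
#' @return [read_panel()] returns an [analyte_panel()];
#'   [write_panel()] returns `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    raw <- as_tibble(raw)
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(
      analyte = readr::col_character(), lloq = readr::col_double(),
      uloq = readr::col_double(), excluded = readr::col_logical()
    ), progress = FALSE)
  }
  need <- c("analyte", "lloq", "uloq", "excluded")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste0("panel file missing columns: ", toString(miss)))
  analyte_panel(raw$analyte, raw$lloq, raw$uloq,
                excluded = raw$analyte[!is.na(raw$excluded) & raw$excluded])
}

#' @rdname read_panel
#' @param panel an [analyte_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "analyte_panel"))
  readr::write_csv(as_tibble(unclass(panel) |> as.data.frame()), path)
  invisible(path)
}
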