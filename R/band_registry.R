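#' Registry of Raman band positions and integration windows
#'
#' Characteristic wavenumbers of the substances tracked in frozen-cell
#' hyperspectral images, with the Gaussian band width used by the phantom
#' generator and the default integration window for rendering heat maps.
#' Positions are literature-standard assignments: amide I (protein backbone)
#' 1655, C-H stretch 2935, O-H stretch of ice/water 3125, cytochrome C 750,
#' DMSO 670, glycerol 850, sucrose 1120 cm^-1. Windows span roughly +/- 3
#' band sigma and are pairwise disjoint so single-band integrals are
#' separable. Edit the returned data frame (or supply your own with the same
#' columns) to change band definitions everywhere downstream; no operation
#' hard-codes a position.
#'
#' @return data.frame with columns `name`, `center` (cm^-1), `sigma` (cm^-1,
#'   Gaussian band sigma), `window_lo`, `window_hi` (cm^-1) and `baseline`
#'   (`"none"` or `"linear"`).
#' @examples
#' default_band_registry()
#' @export
default_band_registry <- function() {
  reg <- data.frame(
    name      = c("dmso", "cytc", "glycerol", "sucrose", "amide_i",
                  "ch_stretch", "oh_ice"),
    center    = c(670, 750, 850, 1120, 1655, 2935, 3125),
    sigma     = c(12, 12, 15, 15, 15, 20, 40),
    stringsAsFactors = FALSE
  )
  reg$window_lo <- reg$center - 3 * reg$sigma
  reg$window_hi <- reg$center + 3 * reg$sigma
  reg$baseline  <- "none"
  reg
}

#' Integration window for one substance
#'
#' @param substance band name present in `registry$name`.
#' @param registry band registry, see [default_band_registry()].
#' @return a `band_window` object (list with `substance`, `lo`, `hi`,
#'   `baseline`).
#' @export
band_window <- function(substance, registry = default_band_registry()) {
  i <- match(substance, registry$name)
  if (is.na(i)) {
    stop("unknown substance '", substance, "'; registry has: ",
         paste(registry$name, collapse = ", "))
  }
  new_band_window(substance, registry$window_lo[i], registry$window_hi[i],
                  registry$baseline[i])
}

#' Construct a band integration window
#'
#' @param substance label for the substance the window belongs to.
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @param baseline `"none"` or `"linear"` (straight line through the window
#'   endpoints, subtracted before integration).
#' @return a `band_window` object.
#' @export
new_band_window <- function(substance, lo, hi, baseline = "none") {
  stopifnot(is.character(substance), length(substance) == 1L,
            is.numeric(lo), is.numeric(hi), length(lo) == 1L,
            length(hi) == 1L)
  if (!lo < hi) stop("band window requires lo < hi (got ", lo, ", ", hi, ")")
  baseline <- match.arg(baseline, c("none", "linear"))
  structure(list(substance = substance, lo = lo, hi = hi,
                 baseline = baseline),
            class = "band_window")
}
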