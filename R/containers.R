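#' Hyperspectral Raman cube
#'
#' A cube holds the intensity array ordered (wavenumber, y, x) together with
#' its strictly increasing wavenumber axis and the physical pixel pitch.
#'
#' @param intensities 3D numeric array, dimensions (wavenumber, y, x).
#' @param wavenumbers strictly increasing numeric vector in cm^-1, length
#'   equal to `dim(intensities)[1]`.
#' @param pixel_pitch pixel edge length in micrometres, > 0.
#' @param meta optional named list carried along (seed, provenance).
#' @return object of class `raman_cube`.
#' @export
raman_cube <- function(intensities, wavenumbers, pixel_pitch, meta = list()) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (length(wavenumbers) != dim(intensities)[1L]) {
    stop("wavenumber axis length (", length(wavenumbers),
         ") must match first cube dimension (", dim(intensities)[1L], ")")
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumber axis must be strictly increasing")
  }
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L ||
      pixel_pitch <= 0) {
    stop("pixel_pitch must be a single positive number (micrometres)")
  }
  if (!all(is.finite(intensities))) stop("cube intensities must be finite")
  structure(list(intensities = intensities,
                 wavenumbers = as.numeric(wavenumbers),
                 pixel_pitch = pixel_pitch, meta = meta),
            class = "raman_cube")
}

#' @export
print.raman_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "raman_cube: %d wavenumbers (%.0f-%.0f cm^-1), %dx%d px @ %.3f um/px\n",
    d[1], min(x$wavenumbers), max(x$wavenumbers), d[2], d[3], x$pixel_pitch))
  invisible(x)
}

#' Per-substance heat map
#'
#' @param values 2D non-negative numeric matrix (y, x).
#' @param substance label of the substance the map renders.
#' @param pixel_pitch pixel pitch in micrometres.
#' @param deconvolved logical, whether the map has been PSF-deconvolved.
#' @param meta optional named list.
#' @return object of class `heat_map`.
#' @export
heat_map <- function(values, substance, pixel_pitch, deconvolved = FALSE,
                     meta = list()) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) stop("heat map values must be finite")
  # tolerate FFT roundoff; anything genuinely negative is an error
  tol <- 1e-9 * max(abs(values), 1e-300)
  if (any(values < -tol)) stop("heat map values must be non-negative")
  values[values < 0] <- 0
  structure(list(values = values, substance = substance,
                 pixel_pitch = pixel_pitch,
                 deconvolved = isTRUE(deconvolved), meta = meta),
            class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("heat_map[%s]: %dx%d px @ %.3f um/px%s, range [%.3g, %.3g]\n",
              x$substance, nrow(x$values), ncol(x$values), x$pixel_pitch,
              if (x$deconvolved) " (deconvolved)" else "",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Cell segmentation masks
#'
#' Boolean masks over one field of view. The ice mask is constrained to lie
#' inside the cell mask.
#'
#' @param cell_mask,ice_mask logical matrices of the same shape; `ice_mask`
#'   may be NULL (treated as all-FALSE).
#' @param pixel_pitch pixel pitch in micrometres.
#' @param extracellular_mask optional logical matrix; defaults to `!cell_mask`.
#' @return object of class `cell_segmentation`.
#' @export
cell_segmentation <- function(cell_mask, ice_mask = NULL, pixel_pitch,
                              extracellular_mask = NULL) {
  stopifnot(is.matrix(cell_mask), is.logical(cell_mask))
  if (is.null(ice_mask)) {
    ice_mask <- array(FALSE, dim(cell_mask))
  }
  stopifnot(identical(dim(ice_mask), dim(cell_mask)))
  if (any(ice_mask & !cell_mask)) {
    stop("ice_mask must be a subset of cell_mask")
  }
  if (is.null(extracellular_mask)) extracellular_mask <- !cell_mask
  stopifnot(identical(dim(extracellular_mask), dim(cell_mask)))
  structure(list(cell_mask = cell_mask, ice_mask = ice_mask,
                 extracellular_mask = extracellular_mask,
                 pixel_pitch = pixel_pitch),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("cell_segmentation: %dx%d px, cell %d px, ice %d px\n",
              nrow(x$cell_mask), ncol(x$cell_mask),
              sum(x$cell_mask), sum(x$ice_mask)))
  invisible(x)
}

#' Calcium-imaging movie
#'
#' @param frames 3D numeric array ordered (t, y, x).
#' @param frame_rate frames per second, > 0.
#' @param stimulus_time stimulus onset in seconds, within the record.
#' @param meta optional named list.
#' @return object of class `calcium_movie`.
#' @export
calcium_movie <- function(frames, frame_rate, stimulus_time, meta = list()) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[1L] < 2L) stop("movie needs at least 2 frames")
  if (!frame_rate > 0) stop("frame_rate must be positive")
  duration <- dim(frames)[1L] / frame_rate
  if (stimulus_time < 0 || stimulus_time > duration) {
    stop("stimulus_time must lie within the record (0-", duration, " s)")
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 stimulus_time = stimulus_time, meta = meta),
            class = "calcium_movie")
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "calcium_movie: %d frames @ %g fps (%.1f s), %dx%d px, stimulus %g s\n",
    d[1], x$frame_rate, d[1] / x$frame_rate, d[2], d[3], x$stimulus_time))
  invisible(x)
}
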