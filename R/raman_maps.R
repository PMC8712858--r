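#' Render a substance heat map by band integration
#'
#' Per-pixel trapezoidal integral of the spectrum over a band window,
#' optionally after subtracting a linear baseline through the window
#' endpoints. Negative integrals (possible after baseline subtraction of a
#' noisy spectrum) are clamped to zero. Units: intensity x cm^-1.
#'
#' @param cube a [raman_cube()].
#' @param window a [band_window()] lying inside the cube's wavenumber range.
#' @return a [heat_map()].
#' @export
integrate_band <- function(cube, window) {
  stopifnot(inherits(cube, "raman_cube"), inherits(window, "band_window"))
  wn <- cube$wavenumbers
  sel <- which(wn >= window$lo & wn <= window$hi)
  if (length(sel) < 2L) {
    stop(sprintf(
      "window [%g, %g] cm^-1 for '%s' overlaps fewer than 2 samples of the cube axis [%g, %g]",
      window$lo, window$hi, window$substance, min(wn), max(wn)))
  }
  x <- wn[sel]
  d <- dim(cube$intensities)
  planes <- matrix(cube$intensities[sel, , ], length(sel), d[2] * d[3])
  # trapezoid weights for a (possibly non-uniform) grid
  w <- numeric(length(x))
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[length(x)] <- dx[length(dx)] / 2
  if (length(x) > 2L) {
    w[2:(length(x) - 1L)] <- (dx[-length(dx)] + dx[-1]) / 2
  }
  vals <- as.vector(w %*% planes)
  if (window$baseline == "linear") {
    vals <- vals - (planes[1L, ] + planes[length(sel), ]) / 2 *
      (x[length(x)] - x[1])
  }
  vals <- pmax(vals, 0)
  heat_map(matrix(vals, d[2], d[3]), window$substance, cube$pixel_pitch,
           meta = list(window = c(window$lo, window$hi),
                       baseline = window$baseline))
}

#' Richardson-Lucy deconvolution of a heat map
#'
#' Restores a heat map with a normalized Gaussian kernel of the given FWHM
#' (the theoretical point spread function of the instrument, expressed in
#' pixels through the map's pixel pitch). The multiplicative update keeps
#' the estimate non-negative and, with circular-boundary convolution,
#' conserves total intensity. If the FWHM is below one pixel the problem is
#' ill-posed at this sampling and the input is returned unchanged with a
#' notice.
#'
#' @param map a [heat_map()] (non-negative).
#' @param psf_fwhm_um PSF full width at half maximum in micrometres, > 0.
#' @param iterations number of Richardson-Lucy iterations; 0 returns the
#'   input unchanged (but flagged deconvolved = FALSE).
#' @return a [heat_map()] with `deconvolved = TRUE` when iterations > 0.
#' @export
deconvolve <- function(map, psf_fwhm_um, iterations = 10L) {
  stopifnot(inherits(map, "heat_map"), psf_fwhm_um > 0, iterations >= 0)
  if (iterations == 0L) return(map)
  if (psf_fwhm_um < map$pixel_pitch) {
    message("PSF FWHM (", psf_fwhm_um, " um) is below one pixel (",
            map$pixel_pitch, " um); deconvolution skipped")
    return(map)
  }
  sigma_px <- psf_fwhm_um / (2 * sqrt(2 * log(2))) / map$pixel_pitch
  kern <- gaussian_kernel(sigma_px)
  obs <- map$values
  est <- obs
  eps <- .Machine$double.eps * max(obs)
  for (i in seq_len(iterations)) {
    blurred <- conv2_circ(est, kern)
    ratio <- obs / pmax(blurred, eps)
    est <- est * conv2_circ(ratio, kern)
  }
  est <- pmax(est, 0)
  heat_map(est, map$substance, map$pixel_pitch, deconvolved = TRUE,
           meta = c(map$meta, list(psf_fwhm_um = psf_fwhm_um,
                                   iterations = iterations)))
}

#' Otsu threshold of a heat map or matrix
#'
#' Values are rescaled to \[0, 1\] before thresholding, so the threshold is
#' invariant to any positive affine rescaling of the input. A constant input
#' has no between-class variance to maximize and is rejected.
#'
#' @param values numeric matrix or [heat_map()].
#' @return logical matrix, TRUE above the Otsu threshold.
#' @export
otsu_mask <- function(values) {
  if (inherits(values, "heat_map")) values <- values$values
  rng <- range(values)
  if (rng[1] == rng[2]) {
    stop("cannot threshold a constant map: no contrast to separate")
  }
  norm <- (values - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256L)
  norm > thr
}

#' Segment the support of one substance
#'
#' Otsu thresholding of the heat map, removal of connected components
#' smaller than `min_object_px`, and hole filling ("thresholding and
#' boundary recognition"). Connectivity is 4-neighbour throughout.
#'
#' @param map a [heat_map()].
#' @param min_object_px smallest component (in pixels) retained.
#' @return logical matrix: the substance mask. An empty mask (everything
#'   below threshold or too small) is a valid result; a constant map is an
#'   error.
#' @export
segment_substance <- function(map, min_object_px = 9L) {
  mask <- otsu_mask(map)
  mask <- remove_small(mask, min_object_px)
  fill_holes(mask)
}

#' Segment the cell from amide I and C-H heat maps
#'
#' The cell is delineated by the amide I and cellular hydrogen-bond (C-H)
#' signals: the filled union of the two substance masks, keeping the largest
#' connected component as the cell (ties broken by smallest (y, x)
#' centroid).
#'
#' @param amide_map,ch_map [heat_map()]s sharing shape and pixel pitch.
#' @param min_object_px passed to [segment_substance()].
#' @return a [cell_segmentation()] with an empty ice mask.
#' @export
segment_cell <- function(amide_map, ch_map, min_object_px = 9L) {
  stopifnot(identical(dim(amide_map$values), dim(ch_map$values)),
            isTRUE(all.equal(amide_map$pixel_pitch, ch_map$pixel_pitch)))
  u <- segment_substance(amide_map, min_object_px) |
    segment_substance(ch_map, min_object_px)
  u <- fill_holes(u)
  if (!any(u)) stop("no cell found: union of amide I and C-H masks is empty")
  cell <- largest_component(u)
  cell_segmentation(cell, NULL, amide_map$pixel_pitch)
}

#' Boundary contour of a mask
#'
#' Pixels of the mask with at least one 4-neighbour outside it.
#'
#' @param mask logical matrix.
#' @return logical matrix marking boundary pixels.
#' @export
mask_boundary <- function(mask) {
  er <- EBImage::erode(mask, EBImage::makeBrush(3L, "diamond")) > 0
  mask & !er
}
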