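# TIFF + JSON sidecar dialect. Multi-page 32-bit float TIFFs hold image
# data scaled into [0, 1] by a per-file `intensity_scale` recorded in the
# sidecar (float TIFF storage is only defined on [0, 1] here); readers
# restore the original scale. Masks are 8-bit label TIFFs.

sidecar_path <- function(tif_path) sub("\\.tif{1,2}$", ".json", tif_path)

write_sidecar <- function(tif_path, meta) {
  jsonlite::write_json(meta, sidecar_path(tif_path), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar <- function(tif_path) {
  jsonlite::read_json(sidecar_path(tif_path), simplifyVector = TRUE)
}

# Affine map of arbitrary finite data into [0, 1] for float TIFF storage;
# offset and scale are recorded in the sidecar and undone on read.
scale_for_tiff <- function(x) {
  lo <- min(x)
  s <- max(max(x) - lo, 1e-300)
  list(offset = lo, scale = s, pages = (x - lo) / s)
}

unscale_tiff <- function(pages, meta) {
  off <- if (is.null(meta$intensity_offset)) 0 else meta$intensity_offset
  pages * meta$intensity_scale + off
}

#' Write / read a Raman cube as multi-page TIFF + JSON sidecar
#'
#' One TIFF page per wavenumber; the sidecar records `wavenumbers_cm1`,
#' `pixel_pitch_um`, `intensity_scale` and any metadata (seed etc.).
#'
#' @param cube a [raman_cube()].
#' @param tif_path output path ending in .tif.
#' @return `write_raman_cube`: the path, invisibly. `read_raman_cube`: a
#'   [raman_cube()].
#' @export
write_raman_cube <- function(cube, tif_path) {
  stopifnot(inherits(cube, "raman_cube"))
  d <- dim(cube$intensities)
  sc <- scale_for_tiff(cube$intensities)
  pages <- lapply(seq_len(d[1]), function(i) sc$pages[i, , ])
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 32L)
  write_sidecar(tif_path, c(list(wavenumbers_cm1 = cube$wavenumbers,
                                 pixel_pitch_um = cube$pixel_pitch,
                                 intensity_scale = sc$scale,
                                 intensity_offset = sc$offset), cube$meta))
  invisible(tif_path)
}

#' @rdname write_raman_cube
#' @export
read_raman_cube <- function(tif_path) {
  meta <- read_sidecar(tif_path)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- unscale_tiff(pages[[i]], meta)
  keep <- setdiff(names(meta),
                  c("wavenumbers_cm1", "pixel_pitch_um", "intensity_scale",
                    "intensity_offset"))
  raman_cube(arr, meta$wavenumbers_cm1, meta$pixel_pitch_um, meta[keep])
}

#' Write / read a heat map as 32-bit float TIFF + JSON sidecar
#'
#' @param map a [heat_map()].
#' @param tif_path output path ending in .tif.
#' @return `write_heat_map`: the path, invisibly. `read_heat_map`: a
#'   [heat_map()].
#' @export
write_heat_map <- function(map, tif_path) {
  stopifnot(inherits(map, "heat_map"))
  sc <- scale_for_tiff(map$values)
  tiff::writeTIFF(sc$pages, tif_path, bits.per.sample = 32L)
  write_sidecar(tif_path, c(list(substance = map$substance,
                                 pixel_pitch_um = map$pixel_pitch,
                                 deconvolved = map$deconvolved,
                                 intensity_scale = sc$scale,
                                 intensity_offset = sc$offset), map$meta))
  invisible(tif_path)
}

#' @rdname write_heat_map
#' @export
read_heat_map <- function(tif_path) {
  meta <- read_sidecar(tif_path)
  v <- unscale_tiff(tiff::readTIFF(tif_path), meta)
  keep <- setdiff(names(meta), c("substance", "pixel_pitch_um",
                                 "deconvolved", "intensity_scale",
                                 "intensity_offset"))
  heat_map(v, meta$substance, meta$pixel_pitch_um, meta$deconvolved,
           meta[keep])
}

#' Write / read segmentation masks as 8-bit label TIFF + JSON sidecar
#'
#' Pages: 1 = cell mask, 2 = ice mask, 3 = extracellular mask.
#'
#' @param seg a [cell_segmentation()].
#' @param tif_path output path ending in .tif.
#' @return `write_segmentation`: the path, invisibly. `read_segmentation`: a
#'   [cell_segmentation()].
#' @export
write_segmentation <- function(seg, tif_path) {
  stopifnot(inherits(seg, "cell_segmentation"))
  pages <- lapply(list(seg$cell_mask, seg$ice_mask, seg$extracellular_mask),
                  function(m) m * 1.0)
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 8L)
  write_sidecar(tif_path, list(pixel_pitch_um = seg$pixel_pitch,
                               pages = c("cell", "ice", "extracellular")))
  invisible(tif_path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(tif_path) {
  meta <- read_sidecar(tif_path)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  cell_segmentation(pages[[1]] > 0.5, pages[[2]] > 0.5,
                    meta$pixel_pitch_um, pages[[3]] > 0.5)
}

#' Write / read a calcium movie as multi-page TIFF + JSON sidecar
#'
#' @param movie a [calcium_movie()].
#' @param tif_path output path ending in .tif.
#' @return `write_calcium_movie`: the path, invisibly. `read_calcium_movie`:
#'   a [calcium_movie()].
#' @export
write_calcium_movie <- function(movie, tif_path) {
  stopifnot(inherits(movie, "calcium_movie"))
  d <- dim(movie$frames)
  sc <- scale_for_tiff(movie$frames)
  pages <- lapply(seq_len(d[1]), function(i) sc$pages[i, , ])
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 32L)
  write_sidecar(tif_path, c(list(frame_rate_hz = movie$frame_rate,
                                 stimulus_time_s = movie$stimulus_time,
                                 intensity_scale = sc$scale,
                                 intensity_offset = sc$offset), movie$meta))
  invisible(tif_path)
}

#' @rdname write_calcium_movie
#' @export
read_calcium_movie <- function(tif_path) {
  meta <- read_sidecar(tif_path)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- unscale_tiff(pages[[i]], meta)
  keep <- setdiff(names(meta),
                  c("frame_rate_hz", "stimulus_time_s", "intensity_scale",
                    "intensity_offset"))
  calcium_movie(arr, meta$frame_rate_hz, meta$stimulus_time_s, meta[keep])
}
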