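#' Simulate a viable/nonviable count table
#'
#' Binomially sampled viable counts per condition and timepoint, emulating
#' dye-exclusion counting of `n_cells` cells during CPA exposure (default
#' timepoints 0, 30 and 60 min).
#'
#' @param true_rates numeric matrix of survival fractions in \[0, 1\], rows =
#'   conditions (rownames used as labels), columns = timepoints; or a named
#'   list of per-condition vectors.
#' @param n_cells cells counted per condition and timepoint.
#' @param timepoints timepoints in minutes, one per column.
#' @param seed RNG seed.
#' @return data.frame with columns condition, timepoint_min, viable,
#'   nonviable (a ViabilityTable).
#' @export
make_viability_table <- function(true_rates, n_cells = 200L,
                                 timepoints = c(0, 30, 60), seed = 1L) {
  if (is.list(true_rates)) {
    true_rates <- do.call(rbind, true_rates)
  }
  if (is.null(dim(true_rates))) true_rates <- matrix(true_rates, nrow = 1L)
  stopifnot(ncol(true_rates) == length(timepoints),
            all(true_rates >= 0), all(true_rates <= 1), n_cells > 0)
  conds <- rownames(true_rates)
  if (is.null(conds)) conds <- paste0("condition_", seq_len(nrow(true_rates)))
  with_seed(seed, {
    rows <- expand.grid(timepoint_min = timepoints, condition = conds,
                        stringsAsFactors = FALSE)[, 2:1]
    p <- as.vector(t(true_rates))
    viable <- stats::rbinom(length(p), n_cells, p)
    data.frame(condition = rows$condition,
               timepoint_min = rows$timepoint_min,
               viable = viable, nonviable = n_cells - viable,
               stringsAsFactors = FALSE)
  })
}

#' Controlled-rate freezing profile
#'
#' The two controlled parameters are the ice nucleation temperature `t_nuc`
#' (deeper = greater undercooling) and the post-nucleation cooling rate
#' `cooling_rate` (B, negative).
#'
#' @param t_nuc nucleation temperature in degrees C, in (-40, 0).
#' @param cooling_rate post-nucleation rate B in degrees C per minute, < 0.
#' @param hold_min hold duration at `t_nuc` in minutes.
#' @return object of class `freeze_profile` with the full segment schedule:
#'   start at 20 C, ramp -10 C/min to `t_nuc`, hold `hold_min`, ramp
#'   `cooling_rate` to -60 C, ramp -10 C/min to -100 C.
#' @export
freeze_profile <- function(t_nuc = -4, cooling_rate = -1, hold_min = 15) {
  stopifnot(t_nuc > -40, t_nuc < 0, cooling_rate < 0, hold_min >= 0)
  segments <- data.frame(
    rate = c(-10, 0, cooling_rate, -10),
    end_temp = c(t_nuc, t_nuc, -60, -100))
  post <- segments$end_temp[segments$rate != 0]
  if (any(diff(post) >= 0)) {
    stop("segment end temperatures must be strictly decreasing")
  }
  structure(list(t_nuc = t_nuc, cooling_rate = cooling_rate,
                 hold_min = hold_min, start_temp = 20, segments = segments),
            class = "freeze_profile")
}

#' Sample-temperature log for a freezing profile
#'
#' Piecewise-linear temperature trace sampled every `sampling_dt` seconds:
#' 20 C, ramp -10 C/min to the nucleation temperature, hold, ramp B to
#' -60 C, ramp -10 C/min to -100 C. The trace is monotone non-increasing
#' after the hold.
#'
#' @param profile a [freeze_profile()].
#' @param sampling_dt sampling interval in seconds.
#' @return data.frame with columns `time_min` and `temperature_c`.
#' @export
make_freeze_log <- function(profile, sampling_dt = 10) {
  stopifnot(inherits(profile, "freeze_profile"), sampling_dt > 0)
  # breakpoints (time in minutes, temperature)
  t0 <- 0; temp0 <- profile$start_temp
  t1 <- t0 + (temp0 - profile$t_nuc) / 10
  t2 <- t1 + profile$hold_min
  t3 <- t2 + (profile$t_nuc - (-60)) / abs(profile$cooling_rate)
  t4 <- t3 + (-60 - (-100)) / 10
  bp_t <- c(t0, t1, t2, t3, t4)
  bp_T <- c(temp0, profile$t_nuc, profile$t_nuc, -60, -100)
  dup <- duplicated(bp_t)  # zero-length hold collapses two breakpoints
  bp_t <- bp_t[!dup]
  bp_T <- bp_T[!dup]
  tt <- sort(unique(c(seq(0, t4, by = sampling_dt / 60), bp_t)))
  data.frame(time_min = tt,
             temperature_c = stats::approx(bp_t, bp_T, xout = tt)$y)
}

#' Synthetic micrograph of suspended disk-shaped cells
#'
#' Bright disks of the given diameters on a dim background, placed on a
#' jittered grid with continuous (sub-pixel) centres so that discretization
#' bias averages out over many cells; optional additive Gaussian noise.
#'
#' @param diameters_um cell diameters in micrometres.
#' @param pixel_pitch micrometres per pixel.
#' @param background,foreground intensity levels.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param seed RNG seed.
#' @return list: `image` (matrix), `pixel_pitch`, `true_diameters_um`.
#' @export
make_cell_micrograph <- function(diameters_um, pixel_pitch = 0.5,
                                 background = 0.1, foreground = 1.0,
                                 noise_sd = 0.02, seed = 1L) {
  stopifnot(all(diameters_um > 0), pixel_pitch > 0)
  r_px <- diameters_um / 2 / pixel_pitch
  pitch <- ceiling(2 * max(r_px)) + 6L
  side <- ceiling(sqrt(length(diameters_um)))
  n <- side * pitch + pitch
  with_seed(seed, {
    img <- matrix(background, n, n)
    for (i in seq_along(diameters_um)) {
      gy <- ((i - 1L) %/% side) * pitch + pitch / 2 + pitch / 2
      gx <- ((i - 1L) %% side) * pitch + pitch / 2 + pitch / 2
      cy <- gy + stats::runif(1, -1, 1)
      cx <- gx + stats::runif(1, -1, 1)
      img[disk_mask(n, n, cy, cx, r_px[i])] <- foreground
    }
    if (noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = noise_sd)
    }
    list(image = img, pixel_pitch = pixel_pitch,
         true_diameters_um = diameters_um)
  })
}
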