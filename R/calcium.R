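#' Detect somata in a calcium movie
#'
#' Local-maxima-based segmentation on the Gaussian-smoothed temporal-maximum
#' projection: a pixel is a soma centre if it is the maximum of its
#' neighbourhood (box of half-width `min_distance`), lies above the Otsu
#' threshold of the smoothed projection, and is at least `min_distance`
#' pixels from any brighter accepted centre (when two maxima are closer, the
#' brighter one wins). Each soma ROI is a disk of `roi_radius` pixels around
#' its centre.
#'
#' @param movie a [calcium_movie()].
#' @param smoothing_sigma Gaussian smoothing sigma in pixels.
#' @param min_distance minimum separation between detections, pixels.
#' @param roi_radius ROI disk radius in pixels.
#' @return list: `centers` (m x 2 matrix of (y, x)), `masks` (list of m
#'   logical matrices), `roi_radius`. Zero detections is a valid empty
#'   result.
#' @export
detect_somata <- function(movie, smoothing_sigma = 2, min_distance = 8L,
                          roi_radius = 2L) {
  stopifnot(inherits(movie, "calcium_movie"))
  d <- dim(movie$frames)
  proj <- temporal_max_projection(movie)
  sm <- conv2_circ(proj, gaussian_kernel(smoothing_sigma))
  if (max(sm) == min(sm)) {
    return(list(centers = matrix(numeric(0), 0, 2), masks = list(),
                roi_radius = roi_radius))
  }
  thr_mask <- otsu_mask(sm)
  win <- 2L * as.integer(min_distance) + 1L
  dil <- EBImage::dilate(sm, EBImage::makeBrush(win, "box"))
  cand <- which(sm == dil & thr_mask, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(list(centers = matrix(numeric(0), 0, 2), masks = list(),
                roi_radius = roi_radius))
  }
  ord <- order(sm[cand], -cand[, 1], -cand[, 2], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- cand[keep, , drop = FALSE]
      if (min((prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2) <
          min_distance^2) ok <- FALSE
    }
    keep[i] <- ok
  }
  centers <- cand[keep, , drop = FALSE]
  centers <- centers[order(centers[, 1], centers[, 2]), , drop = FALSE]
  masks <- lapply(seq_len(nrow(centers)), function(i) {
    disk_mask(d[2], d[3], centers[i, 1], centers[i, 2], roi_radius)
  })
  list(centers = unname(centers), masks = masks, roi_radius = roi_radius)
}

# Pixel-wise maximum over time of a (t, y, x) movie.
temporal_max_projection <- function(movie) {
  d <- dim(movie$frames)
  m <- matrix(movie$frames, d[1], d[2] * d[3])
  out <- m[1L, ]
  for (t in seq_len(d[1])[-1L]) out <- pmax(out, m[t, ])
  matrix(out, d[2], d[3])
}

#' Background ROIs for noise-matched threshold estimation
#'
#' Picks up to `n` disk ROIs of the same radius as the soma ROIs on a
#' regular grid over the field, excluding positions within `exclusion` px of
#' any soma centre, preferring the positions farthest from all somata. Using
#' several noise-matched background ROIs makes the responder threshold the
#' maximum over many background derivative records, keeping the chance that
#' a pure-noise soma trace exceeds it near 1 / (n + 1).
#'
#' @param dim_yx integer (ny, nx) of the field.
#' @param soma_centers m x 2 matrix of (y, x) soma centres.
#' @param n number of ROIs requested.
#' @param roi_radius disk radius in pixels.
#' @param exclusion minimum distance to any soma centre, pixels.
#' @return list of logical ROI masks (possibly fewer than `n`).
#' @export
sample_background_rois <- function(dim_yx, soma_centers, n = 40L,
                                   roi_radius = 3L, exclusion = NULL) {
  if (is.null(exclusion)) exclusion <- 2L * roi_radius + 2L
  step <- 2L * roi_radius + 2L
  ys <- seq(roi_radius + 1L, dim_yx[1] - roi_radius, by = step)
  xs <- seq(roi_radius + 1L, dim_yx[2] - roi_radius, by = step)
  grid <- expand.grid(y = ys, x = xs)
  if (nrow(soma_centers) > 0L) {
    d2 <- vapply(seq_len(nrow(grid)), function(i) {
      min((soma_centers[, 1] - grid$y[i])^2 +
            (soma_centers[, 2] - grid$x[i])^2)
    }, numeric(1))
  } else {
    d2 <- rep(Inf, nrow(grid))
  }
  ok <- d2 >= exclusion^2
  grid <- grid[ok, , drop = FALSE]
  d2 <- d2[ok]
  if (nrow(grid) == 0L) stop("no background positions available")
  ord <- order(-d2, grid$y, grid$x)
  grid <- grid[ord[seq_len(min(n, nrow(grid)))], , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    disk_mask(dim_yx[1], dim_yx[2], grid$y[i], grid$x[i], roi_radius)
  })
}

#' Extract dF/F0 traces from soma ROIs
#'
#' F0 is the background fluorescence of the sample: the time-averaged mean
#' intensity over `background_mask`. For each soma, dff(t) =
#' (mean intensity in its mask at t - F0) / F0.
#'
#' @param movie a [calcium_movie()].
#' @param soma_masks list of logical ROI masks (disjoint from the
#'   background).
#' @param background_mask logical matrix defining the background region.
#' @return list of `calcium_trace` objects: soma_id, centroid (y, x), dff
#'   (numeric vector, one value per frame), f0.
#' @export
extract_dff <- function(movie, soma_masks, background_mask) {
  stopifnot(inherits(movie, "calcium_movie"), is.matrix(background_mask))
  d <- dim(movie$frames)
  m <- matrix(movie$frames, d[1], d[2] * d[3])
  for (sm in soma_masks) {
    if (any(sm & background_mask)) {
      stop("soma masks must be disjoint from the background mask")
    }
  }
  f0 <- mean(m[, as.vector(background_mask), drop = FALSE])
  if (f0 <= 0) stop("background fluorescence F0 is not positive")
  lapply(seq_along(soma_masks), function(i) {
    idx <- which(as.vector(soma_masks[[i]]))
    tr <- rowMeans(m[, idx, drop = FALSE])
    co <- which(soma_masks[[i]], arr.ind = TRUE)
    structure(list(soma_id = i, centroid = c(mean(co[, 1]), mean(co[, 2])),
                   dff = (tr - f0) / f0, f0 = f0),
              class = "calcium_trace")
  })
}

# Max forward-difference derivative of one dff series, in dF/F0 per second.
max_derivative <- function(dff, frame_rate) {
  if (length(dff) < 2L) stop("trace needs at least 2 time points")
  max(diff(dff)) * frame_rate
}

#' Classify responders by the maximum derivative criterion
#'
#' A soma is a responder when the maximum of the first derivative of its
#' dF/F0 trace (forward differences scaled by the frame rate) exceeds a
#' constant threshold determined from the background fluorescence:
#' `threshold_factor` times the largest first derivative observed over the
#' background trace(s).
#'
#' @param traces list of `calcium_trace` objects (from [extract_dff()]).
#' @param background_traces numeric vector (one background dff series) or a
#'   list/matrix of several; the threshold uses the maximum over all.
#' @param frame_rate frames per second.
#' @param threshold_factor multiplier on the background-derived constant
#'   (default 1).
#' @return list: `calls` data.frame (soma_id, max_derivative, threshold,
#'   is_responder), `proportion` responders / total.
#' @export
classify_responders <- function(traces, background_traces, frame_rate,
                                threshold_factor = 1) {
  if (length(traces) == 0L) {
    stop("no traces supplied: responder proportion undefined")
  }
  if (is.numeric(background_traces)) {
    background_traces <- list(background_traces)
  }
  if (is.matrix(background_traces)) {
    background_traces <- asplit(background_traces, 2L)
  }
  bg_max <- max(vapply(background_traces, max_derivative,
                       numeric(1), frame_rate = frame_rate))
  thr <- threshold_factor * bg_max
  md <- vapply(traces, function(tr) max_derivative(tr$dff, frame_rate),
               numeric(1))
  calls <- data.frame(
    soma_id = vapply(traces, `[[`, numeric(1), "soma_id"),
    max_derivative = md, threshold = thr, is_responder = md > thr)
  list(calls = calls, proportion = mean(calls$is_responder))
}

#' End-to-end calcium responder analysis of one movie
#'
#' Soma detection, dF/F0 extraction against a background region (everything
#' farther than the exclusion distance from any soma), responder
#' classification against noise-matched background ROIs.
#'
#' @param movie a [calcium_movie()].
#' @param condition label copied into the summary.
#' @param n_background number of background ROIs for the threshold.
#' @param threshold_factor passed to [classify_responders()].
#' @param background_halo pixels around each soma centre excluded from the
#'   F0 background region, so soma fluorescence tails do not inflate F0.
#' @param ... passed to [detect_somata()].
#' @return list: `centers`, `traces`, `calls`, `summary` (data.frame with
#'   condition, n_somata, n_responders, proportion).
#' @export
analyze_calcium_movie <- function(movie, condition = NA_character_,
                                  n_background = 250L, threshold_factor = 1,
                                  background_halo = 20L, ...) {
  det <- detect_somata(movie, ...)
  if (nrow(det$centers) == 0L) {
    return(list(centers = det$centers, traces = list(), calls = NULL,
                summary = data.frame(condition = condition, n_somata = 0L,
                                     n_responders = 0L, proportion = NA_real_)))
  }
  d <- dim(movie$frames)[2:3]
  bg_rois <- sample_background_rois(d, det$centers, n = n_background,
                                    roi_radius = det$roi_radius)
  roi_union <- Reduce(`|`, c(det$masks, bg_rois))
  halo <- Reduce(`|`, lapply(seq_len(nrow(det$centers)), function(i) {
    disk_mask(d[1], d[2], det$centers[i, 1], det$centers[i, 2],
              background_halo)
  }))
  background_mask <- !roi_union & !halo
  if (!any(background_mask)) background_mask <- !roi_union
  traces <- extract_dff(movie, det$masks, background_mask)
  bg_traces <- extract_dff(movie, bg_rois, background_mask)
  cls <- classify_responders(traces,
                             lapply(bg_traces, `[[`, "dff"),
                             movie$frame_rate, threshold_factor)
  list(centers = det$centers, traces = traces, calls = cls$calls,
       summary = data.frame(condition = condition,
                            n_somata = nrow(det$centers),
                            n_responders = sum(cls$calls$is_responder),
                            proportion = cls$proportion))
}
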