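#' k-nearest-neighbour spatial weights over a pixel mask
#'
#' For every in-mask pixel, its k nearest in-mask pixels by Euclidean
#' distance, ties broken by the neighbour's (y, x) coordinates
#' lexicographically. Weights are row-standardized (each neighbour gets
#' 1/k), so the total weight S0 equals the number of pixels. Pixels are
#' indexed in (y, x) lexicographic order.
#'
#' @param mask logical matrix.
#' @param k neighbour count (8 by default, the instrument study's choice).
#' @return list with `coords` (n x 2 integer matrix, (y, x) sorted
#'   lexicographically), `neighbors` (n x k_eff integer matrix of row
#'   indices into `coords`) and `k` (the effective neighbour count,
#'   min(k, n - 1)).
#' @export
knn_weights <- function(mask, k = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  co <- which(mask, arr.ind = TRUE)
  co <- co[order(co[, 1], co[, 2]), , drop = FALSE]
  n <- nrow(co)
  if (n < 2L) stop("mask must contain at least 2 pixels")
  k_eff <- min(as.integer(k), n - 1L)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[co] <- seq_len(n)
  nbr <- matrix(0L, n, k_eff)

  radius <- 3L
  todo <- seq_len(n)
  while (length(todo) > 0L && radius <= max(dim(mask))) {
    off <- expand.grid(dy = -radius:radius, dx = -radius:radius)
    off <- off[!(off$dy == 0L & off$dx == 0L), ]
    d2 <- off$dy^2 + off$dx^2
    keep <- d2 <= radius^2
    off <- off[keep, ]
    d2 <- d2[keep]
    ord <- order(d2, off$dy, off$dx)
    off <- off[ord, ]
    still <- integer(0)
    for (i in todo) {
      y <- co[i, 1]; x <- co[i, 2]
      found <- 0L
      for (j in seq_len(nrow(off))) {
        yy <- y + off$dy[j]; xx <- x + off$dx[j]
        if (yy < 1L || xx < 1L || yy > nrow(mask) || xx > ncol(mask)) next
        p <- id[yy, xx]
        if (p > 0L) {
          found <- found + 1L
          nbr[i, found] <- p
          if (found == k_eff) break
        }
      }
      if (found < k_eff) {
        still <- c(still, i)
      } else {
        # the k-th neighbour must be closer than the scan radius, otherwise
        # a nearer pixel could lie just outside the scanned disk
        dk <- (co[nbr[i, k_eff], 1] - y)^2 + (co[nbr[i, k_eff], 2] - x)^2
        if (dk > radius^2) still <- c(still, i)
      }
    }
    todo <- still
    radius <- radius * 2L
  }
  if (length(todo) > 0L) {
    # brute force for any stragglers (very sparse masks)
    for (i in todo) {
      d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2
      ord <- order(d2, co[, 1], co[, 2])
      ord <- ord[ord != i]
      nbr[i, ] <- ord[seq_len(k_eff)]
    }
  }
  list(coords = co, neighbors = nbr, k = k_eff)
}

#' Moran's I spatial autocorrelation over a masked image
#'
#' Global Moran's I of the in-mask pixel values with row-standardized
#' k-nearest-neighbour weights:
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2,
#' where S0 = sum w_ij = n for row-standardized weights. Values near +1
#' indicate clustering, values near the null expectation -1/(n-1) indicate
#' spatial randomness, negative values dispersion (checkerboard-like). The
#' result carries the randomization-null expectation and standard deviation.
#'
#' @param map [heat_map()] or numeric matrix.
#' @param mask logical matrix; at least k + 2 in-mask pixels, values not all
#'   equal.
#' @param k neighbour count (default 8).
#' @return object of class `moran_result`: list with `I`, `n`,
#'   `expectation_null` (-1/(n-1)), `sd_null` (randomization), `z`,
#'   `weights_spec`.
#' @export
morans_I <- function(map, mask, k = 8L) {
  vals <- if (inherits(map, "heat_map")) map$values else map
  stopifnot(is.matrix(vals), identical(dim(vals), dim(mask)))
  w <- knn_weights(mask, k)
  n <- nrow(w$coords)
  if (n < k + 2L) {
    stop("Moran's I needs at least k + 2 = ", k + 2L,
         " in-mask pixels (got ", n, ")")
  }
  x <- vals[w$coords]
  if (max(x) == min(x)) {
    stop("degenerate field: in-mask values are all equal (zero variance)")
  }
  xc <- x - mean(x)
  wx <- rowMeans(matrix(xc[w$neighbors], n, w$k))
  I <- sum(xc * wx) / sum(xc^2)

  mom <- moran_null_moments(w, x)
  structure(list(I = I, n = n, expectation_null = mom$expectation,
                 sd_null = mom$sd, z = (I - mom$expectation) / mom$sd,
                 weights_spec = sprintf(
                   "row-standardized %d-NN, Euclidean distance, (y,x) lexicographic tie-break",
                   w$k)),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (n = %d, E[I] = %.4f, sd = %.4f, z = %.2f)\n",
              x$I, x$n, x$expectation_null, x$sd_null, x$z))
  cat(" weights:", x$weights_spec, "\n")
  invisible(x)
}

# Randomization (permutation) null moments of Moran's I for an arbitrary,
# possibly asymmetric weight matrix given as a k-NN neighbour list with
# row-standardized weights. Standard first two moments under random
# permutation of the values over the pixels.
moran_null_moments <- function(w, x) {
  n <- nrow(w$coords)
  k <- w$k
  wt <- 1 / k
  S0 <- n
  # S1 = 1/2 sum_ij (w_ij + w_ji)^2 over the union of directed edges
  i_idx <- rep(seq_len(n), k)
  j_idx <- as.vector(w$neighbors)
  key_ij <- (i_idx - 1) * n + j_idx
  key_ji <- (j_idx - 1) * n + i_idx
  recip <- key_ji %in% key_ij      # does the reverse edge exist?
  S1 <- 0.5 * (sum((wt + wt)^2 * recip) + sum(wt^2 * !recip) * 2)
  col_sums <- tabulate(j_idx, nbins = n) * wt
  S2 <- sum((1 + col_sums)^2)      # row sums are exactly 1
  xc <- x - mean(x)
  m2 <- sum(xc^2) / n
  b2 <- (sum(xc^4) / n) / m2^2
  EI <- -1 / (n - 1)
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  list(expectation = EI, sd = sqrt(max(VI, 0)))
}

#' Intracellular ice metrics
#'
#' Ice area fraction and morphology class. The ice mask is obtained from the
#' O-H/ice heat map by Otsu thresholding restricted to the cell (ice pixels
#' are the above-threshold intracellular pixels), unless the segmentation
#' already carries one and `ice_map` is NULL. The cell is called "chunky"
#' when the largest connected ice component covers at least
#' `chunky_threshold` of the cell area (ice occupying nearly the entire
#' cytoplasmic space, a lethal freezing event), as opposed to small
#' dispersed crystals.
#'
#' @param ice_map [heat_map()] of the ice band, or NULL to use
#'   `seg$ice_mask`.
#' @param seg a [cell_segmentation()] with a nonempty cell mask.
#' @param chunky_threshold fraction of the cell area the largest ice
#'   component must reach (default 0.75).
#' @param min_object_px smallest ice component retained when thresholding.
#' @return list: `ice_area_fraction` in \[0, 1\], `chunky` logical,
#'   `ice_mask` logical matrix.
#' @export
ice_metrics <- function(ice_map = NULL, seg, chunky_threshold = 0.75,
                        min_object_px = 4L) {
  stopifnot(inherits(seg, "cell_segmentation"))
  cell <- seg$cell_mask
  if (!any(cell)) stop("empty cell mask")
  if (is.null(ice_map)) {
    ice <- seg$ice_mask
  } else {
    ice <- otsu_mask(ice_map) & cell
    ice <- remove_small(ice, min_object_px)
  }
  frac <- sum(ice) / sum(cell)
  chunky <- FALSE
  if (any(ice)) {
    big <- sum(largest_component(ice))
    chunky <- big >= chunky_threshold * sum(cell)
  }
  list(ice_area_fraction = frac, chunky = chunky, ice_mask = ice)
}

#' Membrane partitioning ratio of a CPA solute
#'
#' Ratio of the mean solute heat-map value over an extracellular annulus
#' just outside the cell boundary to the mean over the intracellular mask
#' (ice pixels excluded by default, since ice displaces solution). Intensity
#' is taken proportional to concentration. The annulus is `annulus_width`
#' pixels wide and begins `annulus_gap` pixels outside the cell boundary,
#' which avoids boundary blur while staying in the field of view.
#'
#' @param solute_map [heat_map()] of the solute band.
#' @param seg a [cell_segmentation()].
#' @param annulus_gap,annulus_width annulus geometry in pixels.
#' @param exclude_ice drop ice pixels from the intracellular mean.
#' @param floor if > 0, the intracellular mean is floored at this value
#'   instead of failing when it is not positive.
#' @return the dimensionless ratio (extracellular / intracellular).
#' @export
partition_ratio <- function(solute_map, seg, annulus_gap = 2L,
                            annulus_width = 3L, exclude_ice = TRUE,
                            floor = 0) {
  stopifnot(inherits(solute_map, "heat_map"),
            inherits(seg, "cell_segmentation"))
  cell <- seg$cell_mask
  if (!any(cell)) stop("empty cell mask")
  d <- EBImage::distmap(1 - cell)
  annulus <- d > annulus_gap & d <= annulus_gap + annulus_width
  if (!any(annulus)) stop("extracellular annulus is empty")
  inner <- cell
  if (exclude_ice) inner <- inner & !seg$ice_mask
  if (!any(inner)) stop("intracellular mask (excluding ice) is empty")
  m_in <- mean(solute_map$values[inner])
  m_out <- mean(solute_map$values[annulus])
  if (m_in <= 0) {
    if (floor > 0) m_in <- floor
    else stop("intracellular solute mean is not positive; ratio undefined")
  }
  m_out / m_in
}

#' Frozen-cell equivalent diameter
#'
#' Equivalent-circle diameter from the cross-sectional area of the cell
#' mask, D = 2 sqrt(A / pi), and its fraction of the mean fresh-cell
#' diameter (the osmotically driven volume loss readout).
#'
#' @param seg a [cell_segmentation()] with a nonempty cell mask.
#' @param fresh_mean_diameter mean fresh-cell diameter in micrometres, > 0.
#' @return list: `diameter_frozen_um`, `diameter_fraction`.
#' @export
frozen_diameter <- function(seg, fresh_mean_diameter) {
  stopifnot(inherits(seg, "cell_segmentation"), fresh_mean_diameter > 0)
  a_px <- sum(seg$cell_mask)
  if (a_px == 0) stop("empty cell mask: diameter undefined")
  area <- a_px * seg$pixel_pitch^2
  d <- 2 * sqrt(area / pi)
  list(diameter_frozen_um = d, diameter_fraction = d / fresh_mean_diameter)
}

#' C-H / O-H hydration ratio
#'
#' Ratio of the intracellular mean band integral of the C-H stretching peak
#' to that of the broad O-H stretching band; higher values indicate a more
#' dehydrated (less hydrated) cell interior.
#'
#' @param cube a [raman_cube()].
#' @param seg a [cell_segmentation()].
#' @param ch_window,oh_window disjoint [band_window()]s.
#' @return the dimensionless ratio.
#' @export
ch_oh_ratio <- function(cube, seg,
                        ch_window = band_window("ch_stretch"),
                        oh_window = band_window("oh_ice")) {
  if (ch_window$hi >= oh_window$lo && oh_window$hi >= ch_window$lo) {
    stop("C-H and O-H windows must be disjoint")
  }
  ch <- integrate_band(cube, ch_window)
  oh <- integrate_band(cube, oh_window)
  cell <- seg$cell_mask
  if (!any(cell)) stop("empty cell mask")
  denom <- mean(oh$values[cell])
  if (denom <= 0) stop("O-H integral is zero inside the cell; ratio undefined")
  mean(ch$values[cell]) / denom
}

#' Full per-cell cryometrics from one hyperspectral cube
#'
#' Runs the whole frozen-cell pipeline: band integration for each registry
#' substance, optional Richardson-Lucy deconvolution of every map, cell
#' segmentation from the amide I and C-H maps, ice segmentation from the
#' O-H map, then all metrics (ice area and morphology, membrane partition
#' ratio, Moran's I of amide I and cytochrome C, frozen diameter and its
#' fresh-normalized fraction, C-H/O-H ratio).
#'
#' @param cube a [raman_cube()].
#' @param bands band registry (needs at least `amide_i`, `ch_stretch`,
#'   `oh_ice`; `cytc` and the solute band are used when present).
#' @param fresh_mean_diameter_um mean fresh-cell diameter for the
#'   diameter-fraction normalization.
#' @param solute registry band treated as the partitioning CPA solute.
#' @param deconvolve_maps run Richardson-Lucy on every map before
#'   segmentation and metrics (the default; deconvolution always precedes
#'   segmentation in this pipeline).
#' @param psf_fwhm_um,rl_iterations PSF and iteration count for
#'   [deconvolve()].
#' @param chunky_threshold passed to [ice_metrics()].
#' @param cell_id label copied into the output row.
#' @param condition label copied into the output row.
#' @return one-row data.frame: cell_id, condition, ice_area_fraction,
#'   chunky, partition_ratio, moran_amideI, moran_cytc, diameter_frozen_um,
#'   diameter_fraction, ch_oh_ratio.
#' @export
analyze_raman_cube <- function(cube, bands = default_band_registry(),
                               fresh_mean_diameter_um = 19.8,
                               solute = "glycerol",
                               deconvolve_maps = TRUE,
                               psf_fwhm_um = 0.361, rl_iterations = 10L,
                               chunky_threshold = 0.75,
                               cell_id = "cell", condition = NA_character_) {
  need <- c("amide_i", "ch_stretch", "oh_ice")
  if (!all(need %in% bands$name)) {
    stop("band registry must contain: ", paste(need, collapse = ", "))
  }
  maps <- list()
  for (nm in intersect(bands$name, c(need, "cytc", solute))) {
    m <- integrate_band(cube, band_window(nm, bands))
    if (deconvolve_maps) m <- deconvolve(m, psf_fwhm_um, rl_iterations)
    maps[[nm]] <- m
  }
  seg <- segment_cell(maps$amide_i, maps$ch_stretch)
  im <- ice_metrics(maps$oh_ice, seg, chunky_threshold)
  seg <- cell_segmentation(seg$cell_mask, im$ice_mask, seg$pixel_pitch)

  pr <- if (solute %in% names(maps)) {
    partition_ratio(maps[[solute]], seg)
  } else NA_real_
  ma <- morans_I(maps$amide_i, seg$cell_mask)
  mc <- if ("cytc" %in% names(maps)) {
    morans_I(maps$cytc, seg$cell_mask)$I
  } else NA_real_
  fd <- frozen_diameter(seg, fresh_mean_diameter_um)
  ratio <- ch_oh_ratio(cube, seg, band_window("ch_stretch", bands),
                       band_window("oh_ice", bands))
  data.frame(cell_id = cell_id, condition = condition,
             ice_area_fraction = im$ice_area_fraction, chunky = im$chunky,
             partition_ratio = pr, moran_amideI = ma$I, moran_cytc = mc,
             diameter_frozen_um = fd$diameter_frozen_um,
             diameter_fraction = fd$diameter_fraction,
             ch_oh_ratio = ratio, stringsAsFactors = FALSE)
}
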