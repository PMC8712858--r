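#' Specification of a single-cell Raman phantom
#'
#' Ground-truth parameters for one synthetic frozen cell. Defaults describe
#' the study conditions the generator emulates: a large sensory-neuron-sized
#' cell (19.8 um) imaged at 333 nm pixel pitch, moderate dispersed
#' intracellular ice, a cryoprotective solute partitioned 2.4-fold towards
#' the extracellular space, intermediate protein clustering and cytochrome C
#' still mostly mitochondria-localized.
#'
#' @param cell_diameter cell diameter in micrometres.
#' @param ice_fraction fraction of the intracellular area occupied by ice,
#'   in \[0, 1\].
#' @param chunky logical; if TRUE the ice is one large central mass, else
#'   many small separated crystallites totalling `ice_fraction`.
#' @param partition_ratio_true extracellular / intracellular solute
#'   concentration ratio, > 0.
#' @param protein_clustering 0 = spatially uniform amide I field, 1 =
#'   maximally punctate (long-correlation, deep-modulation random field).
#' @param cytc_release 0 = cytochrome C confined to mitochondria-like
#'   puncta, 1 = fully dispersed over the cytoplasm.
#' @param hydration in \[0, 1\], scales the intracellular (non-ice) O-H band.
#' @param noise_level detector noise scale; the additive Gaussian noise sd
#'   per voxel is `noise_level * sqrt(intensity)` (shot-noise surrogate).
#' @param seed integer RNG seed recorded in the cube metadata.
#' @return object of class `cell_phantom_spec`.
#' @export
cell_phantom_spec <- function(cell_diameter = 19.8, ice_fraction = 0.2,
                              chunky = FALSE, partition_ratio_true = 2.4,
                              protein_clustering = 0.5, cytc_release = 0.2,
                              hydration = 0.7, noise_level = 0.05,
                              seed = 1L) {
  frac_ok <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  stopifnot(cell_diameter > 0, frac_ok(ice_fraction),
            frac_ok(protein_clustering), frac_ok(cytc_release),
            frac_ok(hydration), partition_ratio_true > 0, noise_level >= 0)
  structure(list(cell_diameter = cell_diameter, ice_fraction = ice_fraction,
                 chunky = isTRUE(chunky),
                 partition_ratio_true = partition_ratio_true,
                 protein_clustering = protein_clustering,
                 cytc_release = cytc_release, hydration = hydration,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "cell_phantom_spec")
}

#' Synthesize a hyperspectral Raman cube of one frozen cell
#'
#' Forward model: each substance contributes a Gaussian spectral band scaled
#' by a 2D amplitude field; amplitude fields are blurred with a Gaussian PSF
#' (theoretical instrument response, FWHM 0.61 lambda / NA = 361 nm for a
#' 532 nm laser at NA 0.90) and summed into a (wavenumber, y, x) cube, to
#' which shot-noise-like Gaussian noise is added. The wavenumber axis covers
#' the union of the supplied bands' supports (+/- 5 sigma) at `axis_step`
#' spacing, so cubes stay compact when only a subset of bands is requested.
#'
#' Intracellular ice is placed either as one central mass grown outward from
#' the cell centre (chunky) or as a jittered grid of small crystallites with
#' guaranteed gaps, trimmed pixel-by-pixel to the requested total area.
#' Amplitude fields: amide I is a positive random field whose modulation
#' depth and correlation length grow with `protein_clustering`; the C-H
#' field is uniform over the cell; O-H is strong on ice and the frozen
#' extracellular space and scales with `hydration` over the unfrozen
#' cytoplasm; cytochrome C mixes mitochondria-like puncta with a dispersed
#' component according to `cytc_release`; the solute band sits at a uniform
#' intracellular level (zero on ice) and at `partition_ratio_true` times
#' that level outside the cell.
#'
#' @param spec a [cell_phantom_spec()].
#' @param bands band registry rows to synthesize (subset of
#'   [default_band_registry()]); band centres must be separated by more than
#'   4x their widths.
#' @param image_size image edge in pixels (square field of view).
#' @param pixel_pitch pixel pitch in micrometres (default 0.333).
#' @param psf_fwhm_um PSF full width at half maximum in micrometres.
#' @param axis_step wavenumber axis spacing in cm^-1.
#' @param solute which registry band plays the partitioning CPA solute.
#' @return list with elements `cube` (a [raman_cube()]), `truth` (a
#'   [cell_segmentation()] plus true metric values: `ice_fraction`, `chunky`,
#'   `partition_ratio`, `diameter_um`) and `spec`.
#' @export
make_raman_phantom <- function(spec, bands = default_band_registry(),
                               image_size = 72L, pixel_pitch = 0.333,
                               psf_fwhm_um = 0.361, axis_step = 4,
                               solute = "glycerol") {
  stopifnot(inherits(spec, "cell_phantom_spec"))
  n <- as.integer(image_size)
  r_px <- spec$cell_diameter / 2 / pixel_pitch
  if (2 * r_px + 4 > n) {
    stop("cell (", round(2 * r_px, 1), " px) does not fit in a ", n, "x", n,
         " field with a 2-pixel margin; enlarge image_size")
  }
  cs <- sort(bands$center)
  if (length(cs) > 1L) {
    sig <- bands$sigma[order(bands$center)]
    sep <- diff(cs)
    wmax <- pmax(sig[-1], sig[-length(sig)])
    if (any(sep <= 4 * wmax)) {
      stop("band centres must be separated by more than 4x their widths")
    }
  }

  with_seed(spec$seed, {
    cy <- (n + 1) / 2
    cx <- (n + 1) / 2
    cell <- disk_mask(n, n, cy, cx, r_px)
    ice <- place_ice(cell, spec$ice_fraction, spec$chunky, cy, cx)

    amp <- list()
    for (b in seq_len(nrow(bands))) {
      nm <- bands$name[b]
      amp[[nm]] <- switch(
        nm,
        amide_i    = amide_field(cell, spec$protein_clustering),
        ch_stretch = ifelse(cell, 0.8, 0),
        oh_ice     = ifelse(ice, 3.0,
                            ifelse(cell, 1.5 * spec$hydration, 3.0)),
        cytc       = cytc_field(cell, spec$cytc_release, cy, cx, r_px),
        # any other band is treated as the partitioning solute
        solute_field(cell, ice, spec$partition_ratio_true)
      )
      if (nm == solute) {
        amp[[nm]] <- solute_field(cell, ice, spec$partition_ratio_true)
      }
      if (any(amp[[nm]] < 0)) stop("negative amplitude in band ", nm)
    }

    sigma_px <- psf_fwhm_um / (2 * sqrt(2 * log(2))) / pixel_pitch
    kern <- gaussian_kernel(sigma_px)
    amp <- lapply(amp, conv2_circ, kernel = kern)

    wn <- sort(unique(unlist(lapply(seq_len(nrow(bands)), function(b) {
      seq(bands$center[b] - 5 * bands$sigma[b],
          bands$center[b] + 5 * bands$sigma[b], by = axis_step)
    }))))
    planes <- matrix(0, length(wn), n * n)
    for (b in seq_len(nrow(bands))) {
      prof <- exp(-(wn - bands$center[b])^2 / (2 * bands$sigma[b]^2))
      planes <- planes + prof %o% as.vector(amp[[bands$name[b]]])
    }
    if (spec$noise_level > 0) {
      planes <- planes + stats::rnorm(length(planes)) *
        spec$noise_level * sqrt(pmax(planes, 0))
    }

    cube <- raman_cube(array(planes, c(length(wn), n, n)), wn, pixel_pitch,
                       meta = list(seed = spec$seed, solute = solute))
    seg <- cell_segmentation(cell, ice, pixel_pitch)
    truth <- list(segmentation = seg,
                  ice_fraction = sum(ice) / sum(cell),
                  chunky = spec$chunky,
                  partition_ratio = spec$partition_ratio_true,
                  diameter_um = 2 * sqrt(sum(cell) * pixel_pitch^2 / pi))
    list(cube = cube, truth = truth, spec = spec)
  })
}

# --- internal field builders -------------------------------------------------

# Ice mask inside `cell`. Chunky: the round(f * |cell|) in-cell pixels
# closest to the cell centre (ties by (y, x)) -- a single connected mass.
# Dispersed: square crystallites on a jittered grid with >= 2 px gaps,
# trimmed outermost-first (round-robin across blobs) to the exact area.
place_ice <- function(cell, fraction, chunky, cy, cx) {
  target <- round(fraction * sum(cell))
  ice <- array(FALSE, dim(cell))
  if (target <= 0) return(ice)
  idx <- which(cell, arr.ind = TRUE)
  if (chunky) {
    d2 <- (idx[, 1] - cy)^2 + (idx[, 2] - cx)^2
    ord <- order(d2, idx[, 1], idx[, 2])
    sel <- idx[ord[seq_len(target)], , drop = FALSE]
    ice[sel] <- TRUE
    return(ice)
  }
  f <- target / sum(cell)
  # crystallites on a jittered grid of pitch g with 1-px gap lines between
  # s x s blobs (disconnected under the 4-connectivity used throughout);
  # interior coverage is (s/g)^2, so g is sized for the requested fraction
  g <- max(6L, ceiling(1 / (1 - sqrt(min(f, 0.9)))) + 1L)
  oy <- sample.int(g, 1L)
  ox <- sample.int(g, 1L)
  n <- nrow(cell)
  s_lo <- min(max(2L, as.integer(ceiling(g * sqrt(f)))), g - 1L)
  for (s in seq.int(from = s_lo, to = g - 1L)) {
    blobs <- list()
    half_lo <- floor((s - 1L) / 2L)
    half_hi <- ceiling((s - 1L) / 2L)
    for (gy in seq(oy - g, n + g, by = g)) {
      for (gx in seq(ox - g, n + g, by = g)) {
        ylo <- max(1L, gy - half_lo); yhi <- min(n, gy + half_hi)
        xlo <- max(1L, gx - half_lo); xhi <- min(n, gx + half_hi)
        if (ylo > yhi || xlo > xhi) next
        ys <- ylo:yhi
        xs <- xlo:xhi
        sub <- cell[ys, xs, drop = FALSE]
        if (!any(sub)) next
        w <- which(sub, arr.ind = TRUE)
        blobs[[length(blobs) + 1L]] <-
          cbind(y = ys[w[, 1]], x = xs[w[, 2]],
                d2 = (ys[w[, 1]] - gy)^2 + (xs[w[, 2]] - gx)^2)
      }
    }
    total <- sum(vapply(blobs, nrow, integer(1)))
    if (total >= target) {
      # order each blob's pixels innermost-first, then interleave blobs and
      # keep pixels until the target is reached (drops outermost first)
      blobs <- lapply(blobs, function(b) {
        b[order(b[, "d2"], b[, "y"], b[, "x"]), , drop = FALSE]
      })
      nb <- length(blobs)
      counts <- vapply(blobs, nrow, integer(1))
      keep <- integer(nb)
      remaining <- target
      depth <- 0L
      while (remaining > 0L) {
        depth <- depth + 1L
        for (i in seq_len(nb)) {
          if (remaining == 0L) break
          if (keep[i] < counts[i] && depth <= counts[i]) {
            keep[i] <- keep[i] + 1L
            remaining <- remaining - 1L
          }
        }
      }
      for (i in seq_len(nb)) {
        if (keep[i] > 0L) {
          ice[blobs[[i]][seq_len(keep[i]), c("y", "x"), drop = FALSE]] <- TRUE
        }
      }
      return(ice)
    }
  }
  stop("dispersed ice fraction ", signif(f, 3),
       " is not achievable without merging crystallites; use chunky = TRUE")
}

# Positive amide I field: 1 + depth * standardized smoothed white noise,
# clipped at a small positive floor. depth and correlation length both grow
# with the clustering knob; knob = 0 gives an exactly uniform field.
amide_field <- function(cell, clustering) {
  base <- ifelse(cell, 1, 0)
  if (clustering <= 0) return(base)
  z <- matrix(stats::rnorm(length(cell)), nrow(cell))
  L <- 1 + 5 * clustering
  z <- conv2_circ(z, gaussian_kernel(L))
  zc <- z[cell]
  z <- (z - mean(zc)) / stats::sd(zc)
  f <- 1 + 0.6 * clustering * z
  ifelse(cell, pmax(f, 0.05), 0)
}

# Cytochrome C: mix of mitochondria-like puncta and a dispersed component
# with the same total signal, weighted by the release knob.
cytc_field <- function(cell, release, cy, cx, r_px) {
  n <- nrow(cell)
  punct <- array(0, dim(cell))
  n_spots <- 6L
  for (i in seq_len(n_spots)) {
    # rejection-sample a spot centre well inside the cell
    repeat {
      sy <- cy + (stats::runif(1) * 2 - 1) * (r_px - 4)
      sx <- cx + (stats::runif(1) * 2 - 1) * (r_px - 4)
      if ((sy - cy)^2 + (sx - cx)^2 <= (r_px - 4)^2) break
    }
    punct <- punct + disk_mask(n, n, sy, sx, 2.2)
  }
  punct[!cell] <- 0
  mu <- sum(punct) / sum(cell)
  disp <- ifelse(cell, mu, 0)
  (1 - release) * punct + release * disp
}

# Partitioning solute: unit intracellular level (zero on ice, which
# displaces solution), ratio * unit outside the cell.
solute_field <- function(cell, ice, ratio) {
  f <- ifelse(cell, 1, ratio)
  f[ice] <- 0
  f
}
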