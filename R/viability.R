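#' Fresh-cell diameters from a micrograph
#'
#' Equivalent-circle diameter of every cell in a brightfield/fluorescence
#' micrograph: Otsu thresholding, connected-component labelling,
#' small-object rejection, then D = 2 sqrt(A / pi) with A the component area
#' in square micrometres.
#'
#' @param image numeric intensity matrix.
#' @param pixel_pitch micrometres per pixel, > 0.
#' @param min_object_px smallest component retained (debris rejection).
#' @return numeric vector of diameters in micrometres (empty if no cells).
#' @export
fresh_diameter <- function(image, pixel_pitch, min_object_px = 20L) {
  stopifnot(is.matrix(image), pixel_pitch > 0)
  if (max(image) == min(image)) return(numeric(0))
  mask <- otsu_mask(image)
  mask <- fill_holes(remove_small(mask, min_object_px))
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0L) return(numeric(0))
  areas <- tabulate(lab[lab > 0], nbins = max(lab)) * pixel_pitch^2
  2 * sqrt(areas / pi)
}

# Wilson 95% score interval for x successes out of n (no continuity
# correction; well-behaved near 0 and 1).
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Survival curves from a viability count table
#'
#' Per-condition fraction viable over timepoints with Wilson 95% confidence
#' intervals.
#'
#' @param table data.frame with columns condition, timepoint_min, viable,
#'   nonviable (counts >= 0, unique condition/timepoint pairs).
#' @param conf confidence level.
#' @return data.frame: condition, timepoint_min, fraction_viable, ci_lower,
#'   ci_upper, n.
#' @export
survival_curve <- function(table, conf = 0.95) {
  need <- c("condition", "timepoint_min", "viable", "nonviable")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(table$viable < 0) || any(table$nonviable < 0)) {
    stop("counts must be non-negative")
  }
  key <- paste(table$condition, table$timepoint_min)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, timepoint) rows: ", key[duplicated(key)][1])
  }
  tot <- table$viable + table$nonviable
  if (any(tot == 0)) {
    i <- which(tot == 0)[1]
    stop("zero total count in row (", table$condition[i], ", ",
         table$timepoint_min[i], " min)")
  }
  ci <- t(mapply(wilson_ci, table$viable, tot, MoreArgs = list(conf = conf)))
  out <- data.frame(condition = table$condition,
                    timepoint_min = table$timepoint_min,
                    fraction_viable = table$viable / tot,
                    ci_lower = ci[, 1], ci_upper = ci[, 2], n = tot,
                    stringsAsFactors = FALSE)
  out[order(out$condition, out$timepoint_min), , drop = FALSE]
}

#' Post-thaw recovery rate
#'
#' Percent ratio of the viable cell count immediately after thawing to the
#' viable cell count immediately before CPA addition pre-freeze. May exceed
#' 100 (reported with a notice, not clamped).
#'
#' @param viable_post_thaw,viable_pre_cpa viable counts; the denominator
#'   must be positive.
#' @return percentage.
#' @export
recovery_rate <- function(viable_post_thaw, viable_pre_cpa) {
  if (viable_pre_cpa <= 0) stop("pre-CPA viable count must be positive")
  out <- 100 * viable_post_thaw / viable_pre_cpa
  if (out > 100) message("recovery rate exceeds 100% (", round(out, 1), "%)")
  out
}

#' Post-thaw attachment rate
#'
#' Percent ratio of adhered, metabolically active culture signal 24 h after
#' thawing to that of a fresh-cell control 24 h after passaging.
#'
#' @param signal_post_thaw,signal_fresh_control intensities; the control
#'   must be positive.
#' @return percentage.
#' @export
attachment_rate <- function(signal_post_thaw, signal_fresh_control) {
  if (signal_fresh_control <= 0) stop("fresh control signal must be positive")
  100 * signal_post_thaw / signal_fresh_control
}

#' PDA excimer-to-monomer membrane fluidity ratio
#'
#' Relative membrane fluidity from pyrenedecanoic-acid fluorescence:
#' excimer emission (460 nm) divided by monomer emission (400 nm).
#'
#' @param emission_400 monomer intensity at 400 nm, > 0.
#' @param emission_460 excimer intensity at 460 nm, > 0.
#' @return dimensionless ratio.
#' @export
fluidity_ratio <- function(emission_400, emission_460) {
  if (emission_400 <= 0) stop("monomer emission (400 nm) must be positive")
  if (emission_460 <= 0) stop("excimer emission (460 nm) must be positive")
  emission_460 / emission_400
}
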