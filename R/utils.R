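# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Logical disk mask: TRUE where (row - cy)^2 + (col - cx)^2 <= r^2,
# pixel centres at integer coordinates.
disk_mask <- function(nrow, ncol, cy, cx, radius) {
  dy <- (seq_len(nrow) - cy)^2
  dx <- (seq_len(ncol) - cx)^2
  outer(dy, dx, `+`) <= radius^2
}

# Odd-sized normalized Gaussian kernel for spatial convolution.
gaussian_kernel <- function(sigma_px, size = NULL) {
  if (is.null(size)) size <- 2L * max(3L, ceiling(4 * sigma_px)) + 1L
  if (size %% 2L == 0L) size <- size + 1L
  r <- (size - 1L) / 2L
  g <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

# Circular (wrap-around) convolution; conserves total mass exactly.
# Kernels larger than the image are centre-cropped and renormalized.
conv2_circ <- function(x, kernel) {
  kd <- dim(kernel)
  lim <- dim(x) - 1L + dim(x) %% 2L  # largest odd size fitting each axis
  if (any(kd > lim)) {
    keep <- pmin(kd, lim)
    r0 <- (kd - keep) %/% 2L
    kernel <- kernel[r0[1] + seq_len(keep[1]), r0[2] + seq_len(keep[2]),
                     drop = FALSE]
    kernel <- kernel / sum(kernel)
  }
  EBImage::filter2(x, kernel, boundary = "circular")
}

# Trapezoidal integral of y over x (both numeric vectors, x increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Largest connected component of a logical mask (8-connectivity); ties in
# size broken by the smallest (y, x) centroid, lexicographically.
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  if (n == 1L) return(lab == 1L)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    cent <- t(vapply(best, function(i) {
      w <- which(lab == i, arr.ind = TRUE)
      c(mean(w[, 1]), mean(w[, 2]))
    }, numeric(2)))
    best <- best[order(cent[, 1], cent[, 2])][1L]
  }
  lab == best[1L]
}

# Remove connected components smaller than min_px (8-connectivity).
remove_small <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_px)
  array(lab %in% keep, dim(mask))
}

# Fill holes of a logical mask.
fill_holes <- function(mask) {
  EBImage::fillHull(mask) > 0
}
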