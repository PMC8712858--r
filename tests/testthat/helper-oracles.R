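# Independent oracles and small shared fixtures, kept deliberately naive.

# Brute-force Moran's I: full distance matrix, k nearest with (y, x)
# lexicographic tie-break, row-standardized weights, exhaustive double sum.
brute_moran <- function(vals, mask, k = 8L) {
  co <- which(mask, arr.ind = TRUE)
  co <- co[order(co[, 1], co[, 2]), , drop = FALSE]
  n <- nrow(co)
  x <- vals[co]
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2
    ord <- order(d2, co[, 1], co[, 2])
    ord <- ord[ord != i]
    W[i, ord[seq_len(min(k, n - 1L))]] <- 1 / min(k, n - 1L)
  }
  xc <- x - mean(x)
  (n / sum(W)) * sum(W * outer(xc, xc)) / sum(xc^2)
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Reduced band registry for fast phantom tests.
test_bands <- function(names = c("amide_i", "ch_stretch", "oh_ice",
                                 "glycerol")) {
  reg <- default_band_registry()
  reg[reg$name %in% names, , drop = FALSE]
}

# Match each detected centre to the nearest ground-truth soma; returns the
# truth responder labels in detection order.
match_truth_labels <- function(centers, truth) {
  vapply(seq_len(nrow(centers)), function(i) {
    truth$is_responder[which.min((truth$y - centers[i, 1])^2 +
                                   (truth$x - centers[i, 2])^2)]
  }, logical(1))
}

# Distance from each detected centre to its nearest true soma.
match_truth_dist <- function(centers, truth) {
  vapply(seq_len(nrow(centers)), function(i) {
    sqrt(min((truth$y - centers[i, 1])^2 + (truth$x - centers[i, 2])^2))
  }, numeric(1))
}
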