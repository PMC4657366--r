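# Independent oracles used across the suite. Each is deliberately written
# the slow, obvious way (loops, explicit histograms) so it shares no code
# with the implementation it checks.

# 8-connected component count by breadth-first flood fill.
count_components <- function(m) {
  on <- m == 1
  visited <- matrix(FALSE, nrow(m), ncol(m))
  idx <- which(on, arr.ind = TRUE)
  n <- 0L
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (visited[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); visited[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && b >= 1 && a <= nrow(m) && b <= ncol(m) &&
            on[a, b] && !visited[a, b]) {
          visited[a, b] <- TRUE
          queue[[length(queue) + 1L]] <- c(a, b)
        }
      }
    }
  }
  n
}

# Mutual information by explicit histogram tallies and the triple-sum
# formula MI = sum_ij p_ij log2( p_ij / (p_i q_j) ).
mi_triple_sum <- function(a, b, n_bins = 64, lo = 0, hi = 255) {
  binof <- function(v) {
    i <- floor((v - lo) * (n_bins / (hi - lo)))
    min(max(i, 0), n_bins - 1) + 1
  }
  joint <- matrix(0, n_bins, n_bins)
  for (k in seq_along(a)) {
    joint[binof(a[k]), binof(b[k])] <- joint[binof(a[k]), binof(b[k])] + 1
  }
  p <- joint / sum(joint)
  pi_ <- rowSums(p); qj <- colSums(p)
  mi <- 0
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (pi_[i] * qj[j]))
  }
  mi
}

# Quadruple-loop spatial correlation of two log-polar grids: circular over
# rows (angle), linear over columns (log-radius).
brute_lp_correlation <- function(ref, tgt, u, v) {
  na <- nrow(ref); nr <- ncol(ref)
  s <- 0
  for (i in 0:(na - 1)) for (j in 0:(nr - 1)) {
    jj <- j + v
    if (jj >= 0 && jj <= nr - 1) {
      s <- s + ref[i + 1, j + 1] * tgt[(i + u) %% na + 1, jj + 1]
    }
  }
  s
}

# Per-pixel loop version of the 17-feature computation.
loop_features <- function(raster, mask = NULL, laterality = "OD") {
  m <- raster$valid_mask
  if (!is.null(mask)) m <- m & (if (inherits(mask, "overlap_mask")) mask$mask else mask)
  size <- nrow(raster$pixels)
  ctr <- (size - 1) / 2
  nms <- c("all_rings", "temporal", "superior", "nasal", "inferior",
           sprintf("hour_%02d", 1:12))
  sums <- stats::setNames(numeric(17), nms); ns <- sums
  for (yy in seq_len(size)) for (xx in seq_len(size)) {
    if (!m[yy, xx]) next
    x <- xx - 1 - ctr; y <- yy - 1 - ctr
    if (laterality == "OS") x <- -x
    psi <- atan2(-y, x) * 180 / pi
    v <- raster$pixels[yy, xx]
    sums[1] <- sums[1] + v; ns[1] <- ns[1] + 1
    q <- c("nasal", "superior", "temporal", "inferior")[
      floor(((psi + 45) %% 360) / 90) + 1]
    sums[q] <- sums[q] + v; ns[q] <- ns[q] + 1
    h <- sprintf("hour_%02d", ((floor((90 - psi) / 30 + 0.5) - 1) %% 12) + 1)
    sums[h] <- sums[h] + v; ns[h] <- ns[h] + 1
  }
  sums / ns
}
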